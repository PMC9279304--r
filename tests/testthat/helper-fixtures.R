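# Fixture builders: everything is generated in code at test time.

tiny_labels <- function(d = c(10, 10, 10), C = 6, seed = 1, spacing = c(1, 1, 1)) {
  lab <- withr::with_seed(seed, array(sample(0:(C - 1), prod(d), TRUE), d))
  label_volume(lab, C, spacing)
}

# minimal explicit-VR little-endian DICOM slice writer (one slice per file),
# mirroring the subset the reader supports
write_test_dicom_slice <- function(path, pixels, sx, sy, ipp) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  elem <- function(group, el, vr, bytes) {
    writeBin(writeBin(c(group, el), raw(), size = 2, endian = "little"), con)
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      writeBin(raw(2), con)
      writeBin(as.integer(length(bytes)), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(length(bytes)), con, size = 2, endian = "little")
    }
    writeBin(bytes, con)
  }
  str_bytes <- function(s) { # even length, space padded
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
    b
  }
  us_bytes <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  rows <- ncol(pixels); cols <- nrow(pixels) # (x = col index, y = row index)
  elem(0x0020L, 0x0032L, "DS", str_bytes(paste(ipp, collapse = "\\")))
  elem(0x0028L, 0x0010L, "US", us_bytes(rows))
  elem(0x0028L, 0x0011L, "US", us_bytes(cols))
  elem(0x0028L, 0x0030L, "DS", str_bytes(sprintf("%g\\%g", sy, sx)))
  elem(0x0028L, 0x0100L, "US", us_bytes(16L))
  elem(0x0028L, 0x0103L, "US", us_bytes(1L))
  px <- writeBin(as.integer(round(as.vector(pixels))), raw(), size = 2,
                 endian = "little")
  elem(0x7FE0L, 0x0010L, "OW", px)
}

write_test_dicom_series <- function(dir, arr, spacing, z0 = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(dim(arr)[3])) {
    write_test_dicom_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                           arr[, , k], sx = spacing[1], sy = spacing[2],
                           ipp = c(0, 0, z0 + (k - 1) * spacing[3]))
  }
  dir
}

# digitized axis-aligned shapes for morphometry oracles (1-based voxel grid,
# voxel centre (i,j,k) at 0-based mm coordinate (i-1)*s)
digitize_cylinder <- function(d, spacing, r_mm, z_range_mm, centre_mm) {
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    z <- (k - 1) * spacing[3]
    if (z < z_range_mm[1] || z > z_range_mm[2]) next
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      x <- (i - 1) * spacing[1]; y <- (j - 1) * spacing[2]
      out[i, j, k] <- (x - centre_mm[1])^2 + (y - centre_mm[2])^2 <= r_mm^2
    }
  }
  out
}

digitize_sphere <- function(d, spacing, r_mm, centre_mm) {
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  x <- (g$i - 1) * spacing[1]; y <- (g$j - 1) * spacing[2]
  z <- (g$k - 1) * spacing[3]
  array((x - centre_mm[1])^2 + (y - centre_mm[2])^2 + (z - centre_mm[3])^2 <= r_mm^2, d)
}
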