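# Minimal DICOM series reader.
#
# Supports the subset needed for CBCT geometry: explicit-VR little-endian
# files with uncompressed 16-bit PixelData, one slice per file. Tags read:
# Rows, Columns, PixelSpacing, ImagePositionPatient, SliceLocation,
# BitsAllocated, PixelRepresentation, RescaleSlope/Intercept, PixelData.
# Slices are sorted by their z position; inconsistent inter-slice spacing is
# an error.

.dcm_read_elements <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  # optional 128-byte preamble + "DICM"
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else { # implicit VR fallback
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295 || pos + hdr + len - 1L > length(raw)) break
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr, bytes = raw[(pos + hdr):(pos + hdr + len - 1L)])
    pos <- pos + hdr + len
    if (key == "7fe0,0010") break
  }
  out
}

.dcm_str <- function(el) if (is.null(el)) NULL else trimws(rawToChar(el$bytes))
.dcm_num <- function(el) {
  s <- .dcm_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_u16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", size = 2, signed = FALSE, endian = "little")
}

.dcm_read_slice <- function(path) {
  el <- .dcm_read_elements(path)
  rows <- .dcm_u16(el[["0028,0010"]])
  cols <- .dcm_u16(el[["0028,0011"]])
  if (is.null(rows) || is.null(cols)) stopf("%s: missing Rows/Columns", path)
  ps <- .dcm_num(el[["0028,0030"]]) # (row spacing = y, column spacing = x)
  if (is.null(ps) || length(ps) != 2L) stopf("%s: missing PixelSpacing", path)
  ipp <- .dcm_num(el[["0020,0032"]])
  zpos <- if (!is.null(ipp) && length(ipp) == 3L) ipp[3]
          else .dcm_num(el[["0020,1041"]])
  if (is.null(zpos)) stopf("%s: no slice position (IPP or SliceLocation)", path)
  bits <- .dcm_u16(el[["0028,0100"]]) %||% 16L
  if (bits != 16L) stopf("%s: only 16-bit PixelData supported", path)
  signed <- (.dcm_u16(el[["0028,0103"]]) %||% 1L) == 1L
  px <- el[["7fe0,0010"]]
  if (is.null(px)) stopf("%s: no PixelData", path)
  v <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
               signed = signed, endian = "little")
  slope <- (.dcm_num(el[["0028,1053"]]) %||% 1)[1]
  inter <- (.dcm_num(el[["0028,1052"]]) %||% 0)[1]
  v <- v * slope + inter
  # PixelData is row-major (row by row); x = column index, y = row index
  list(data = matrix(v, nrow = cols), sx = ps[2], sy = ps[1], z = zpos[1],
       ox = if (!is.null(ipp)) ipp[1] else 0,
       oy = if (!is.null(ipp)) ipp[2] else 0)
}

#' Read a DICOM series directory into a volume
#'
#' @param dir directory containing the `.dcm` slices of one series.
#' @param tol relative tolerance on inter-slice spacing consistency.
#' @return a `cbct_volume`; slice spacing is derived from slice z positions.
#' @export
read_dicom_series <- function(dir, tol = 1e-3) {
  if (!dir.exists(dir)) stopf("no such directory: %s", dir)
  files <- list.files(dir, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) stopf("%s: need at least 2 slices", dir)
  slices <- lapply(files, .dcm_read_slice)
  z <- vapply(slices, `[[`, numeric(1), "z")
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dz <- diff(z)
  if (any(dz <= 0)) stopf("%s: duplicate slice positions", dir)
  if ((max(dz) - min(dz)) > tol * mean(dz))
    stopf("%s: inconsistent slice spacing (%.5g..%.5g mm)", dir, min(dz), max(dz))
  d1 <- dim(slices[[1]]$data)
  arr <- array(0, c(d1, length(slices)))
  for (k in seq_along(slices)) {
    if (!identical(dim(slices[[k]]$data), d1))
      stopf("%s: slice dimensions differ within series", dir)
    arr[, , k] <- slices[[k]]$data
  }
  s1 <- slices[[1]]
  volume(arr, spacing = c(s1$sx, s1$sy, mean(dz)),
         origin = c(s1$ox, s1$oy, z[1]))
}
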