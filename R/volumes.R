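#' Volumetric image containers
#'
#' A `cbct_volume` holds a 3D scalar intensity grid together with its physical
#' voxel spacing in mm and an origin. Arrays use R's column-major `(x, y, z)`
#' order: `data[, , k]` is the k-th axial slice, `spacing = c(sx, sy, sz)`.
#' The physical centre of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, mm per voxel, all > 0.
#' @param origin numeric length-3, mm coordinates of the first voxel centre.
#' @return an object of class `cbct_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite numbers (mm)")
  if (any(!is.finite(data))) stopf("volume intensities must all be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "cbct_volume")
}

#' Multiclass label volume
#'
#' Integer class labels on a voxel grid. The default scheme has six classes:
#' 0 background, 1 upper skull, 2 mandible, 3 maxillary teeth,
#' 4 mandibular teeth, 5 airway.
#'
#' @param labels integer 3D array with values in `0:(num_classes - 1)`.
#' @param num_classes number of classes C including background.
#' @param spacing,origin as in [volume()].
#' @return an object of class `cbct_labels`.
#' @export
label_volume <- function(labels, num_classes = 6L, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3D array")
  num_classes <- as.integer(num_classes)
  rng <- range(labels)
  if (rng[1] < 0 || rng[2] > num_classes - 1L)
    stopf("labels must lie in [0, %d]", num_classes - 1L)
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 num_classes = num_classes,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "cbct_labels")
}

#' Names of the default segmentation classes
#' @return character vector of length 6 in fixed channel order.
#' @export
class_names <- function() {
  c("background", "upper_skull", "mandible", "maxillary_teeth",
    "mandibular_teeth", "airway")
}

#' @export
print.cbct_volume <- function(x, ...) {
  cat(sprintf("<cbct_volume> %s voxels, spacing %s mm, intensity [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.cbct_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:(x$num_classes - 1L)))
  cat(sprintf("<cbct_labels> %s voxels, %d classes, spacing %s mm\n",
              paste(dim(x$labels), collapse = "x"), x$num_classes,
              paste(format(x$spacing), collapse = "x")))
  cat("  voxels per class:", paste(sprintf("%s=%d", names(tab), tab),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Read a volumetric image
#'
#' Reads a NIfTI file or a directory holding one DICOM series into a
#' [volume()] (or [label_volume()] for integer NIfTI label maps via
#' `read_labels()`). Spacing is taken from file metadata.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`; default guesses from `path`.
#' @return a `cbct_volume`.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stopf("no such file: %s", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stopf("expected a 3D image, got %dD", length(dim(arr)))
    sp <- RNifti::pixdim(img)[1:3]
    org <- tryCatch(RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
    volume(arr, spacing = sp, origin = org)
  } else {
    read_dicom_series(path)
  }
}

#' Read a NIfTI label map
#' @param path NIfTI file.
#' @param num_classes number of classes C.
#' @return a `cbct_labels`.
#' @export
read_labels <- function(path, num_classes = 6L) {
  v <- read_volume(path, "nifti")
  label_volume(round(v$data), num_classes = num_classes,
               spacing = v$spacing, origin = v$origin)
}

#' Write a volume or label map to NIfTI
#' @param x a `cbct_volume`, `cbct_labels` or `cbct_soft_labels`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "cbct_volume")) x$data
         else if (inherits(x, "cbct_labels")) x$labels
         else if (inherits(x, "cbct_soft_labels")) x$probs
         else stopf("cannot write object of class %s", class(x)[1])
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(x$spacing, length.out = length(dim(arr)))[1:3]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max intensity normalization within a fixed window
#'
#' Clips intensities to `window` and rescales linearly so the window maps to
#' `[0, 1]`. The default window (-1000, 2000) spans air to dense bone/teeth in
#' (uncalibrated, HU-like) CBCT units.
#'
#' @param v a `cbct_volume`.
#' @param window length-2 numeric `(lo, hi)`, `hi > lo`.
#' @return a normalized `cbct_volume` with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(v, window = c(-1000, 2000)) {
  stopifnot(inherits(v, "cbct_volume"))
  lo <- window[1]; hi <- window[2]
  if (!(hi > lo)) stopf("degenerate window: hi (%g) must exceed lo (%g)", hi, lo)
  out <- (clamp(v$data, lo, hi) - lo) / (hi - lo)
  volume(out, v$spacing, v$origin)
}

# ---- resampling core ------------------------------------------------------

# continuous 0-based input indices of the output voxel centres along one axis
.axis_coords <- function(n_in, sp_in, sp_out) {
  n_out <- max(1L, as.integer(ceiling(n_in * sp_in / sp_out)))
  idx <- ((seq_len(n_out) - 1) * sp_out) / sp_in
  clamp(idx, 0, n_in - 1) # edge clamp
}

# gather arr at continuous 0-based coordinates (same-length vectors cx, cy, cz)
sample_trilinear <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  cx <- clamp(cx, 0, d[1] - 1); cy <- clamp(cy, 0, d[2] - 1); cz <- clamp(cz, 0, d[3] - 1)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(ix, iy, iz) arr[1L + ix + d[1] * (iy + d[2] * iz)]
  v <- (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
                   fy       * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
       fz       * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
                   fy       * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
  v
}

sample_nearest <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  ix <- clamp(round(cx), 0, d[1] - 1)
  iy <- clamp(round(cy), 0, d[2] - 1)
  iz <- clamp(round(cz), 0, d[3] - 1)
  arr[1L + ix + d[1] * (iy + d[2] * iz)]
}

resample_array <- function(arr, spacing, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  ax <- .axis_coords(d[1], spacing[1], target_spacing[1])
  ay <- .axis_coords(d[2], spacing[2], target_spacing[2])
  az <- .axis_coords(d[3], spacing[3], target_spacing[3])
  nd <- c(length(ax), length(ay), length(az))
  cx <- rep(ax, times = nd[2] * nd[3])
  cy <- rep(rep(ay, each = nd[1]), times = nd[3])
  cz <- rep(az, each = nd[1] * nd[2])
  v <- if (mode == "linear") sample_trilinear(arr, cx, cy, cz)
       else sample_nearest(arr, cx, cy, cz)
  array(v, nd)
}

#' Spacing-aware resampling
#'
#' Resamples a volume or label map to a new voxel spacing, sampling at output
#' voxel centres. Output shape is `ceiling(shape * spacing / target)` so the
#' physical extent is fully covered; out-of-range samples use edge clamping.
#' Label maps always use nearest-neighbour interpolation.
#'
#' @param v a `cbct_volume` or `cbct_labels`.
#' @param target_spacing numeric length 1 (isotropic) or 3, mm.
#' @param mode `"linear"` (default for volumes) or `"nearest"`.
#' @return resampled object of the same class.
#' @export
resample <- function(v, target_spacing, mode = c("linear", "nearest")) {
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stopf("target_spacing must be positive")
  if (inherits(v, "cbct_labels")) {
    out <- resample_array(v$labels, v$spacing, target_spacing, "nearest")
    return(label_volume(out, v$num_classes, target_spacing, v$origin))
  }
  mode <- match.arg(mode)
  stopifnot(inherits(v, "cbct_volume"))
  if (isTRUE(all.equal(v$spacing, as.numeric(target_spacing))))
    return(v)
  out <- resample_array(v$data, v$spacing, target_spacing, mode)
  volume(out, target_spacing, v$origin)
}
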