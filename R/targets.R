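#' Soft (probabilistic) label volume
#'
#' Per-voxel class probability field stored as a 4D array `(x, y, z, C)`.
#' Probabilities are nonnegative and sum to 1 over channels at every voxel.
#' Channel order is fixed: background, upper skull, mandible, maxillary teeth,
#' mandibular teeth, airway.
#'
#' @param probs 4D numeric array `(x, y, z, C)`.
#' @param spacing,origin as in [volume()].
#' @return an object of class `cbct_soft_labels`.
#' @export
soft_labels <- function(probs, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(probs)) != 4L) stopf("probs must be a 4D (x,y,z,C) array")
  if (min(probs) < -1e-8) stopf("probabilities must be nonnegative")
  structure(list(probs = probs, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "cbct_soft_labels")
}

#' @export
print.cbct_soft_labels <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<cbct_soft_labels> %s voxels, %d channels, spacing %s mm\n",
              paste(d[1:3], collapse = "x"), d[4],
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

# one-hot encode an integer label array to (x,y,z,C)
one_hot <- function(labels, num_classes) {
  d <- dim(labels)
  out <- array(0, c(d, num_classes))
  v <- prod(d)
  out[seq_len(v) + v * as.numeric(labels)] <- 1
  out
}

#' Coarse soft targets from ground-truth labels
#'
#' One-hot encodes a label volume to C channels and linearly interpolates each
#' channel to the coarse spacing, producing per-voxel class probability
#' distributions ("soft targets") for coarse-stage training. Trilinear
#' interpolation is linear, so channel sums stay 1 up to float round-off.
#'
#' @param gt a `cbct_labels` ground-truth volume.
#' @param coarse_spacing target spacing in mm (scalar isotropic or length 3);
#'   must be >= the input spacing componentwise (downscaling).
#' @return a `cbct_soft_labels` at `coarse_spacing`.
#' @export
make_soft_targets <- function(gt, coarse_spacing = 1.0) {
  stopifnot(inherits(gt, "cbct_labels"))
  if (length(coarse_spacing) == 1L) coarse_spacing <- rep(coarse_spacing, 3L)
  if (any(coarse_spacing < gt$spacing - 1e-9))
    stopf("coarse_spacing must be >= input spacing (downscaling only)")
  if (prod(dim(gt$labels)) == 0L) stopf("empty label volume")
  oh <- one_hot(gt$labels, gt$num_classes)
  ch <- lapply(seq_len(gt$num_classes), function(c)
    resample_array(oh[, , , c], gt$spacing, coarse_spacing, "linear"))
  probs <- array(unlist(ch, use.names = FALSE), c(dim(ch[[1]]), gt$num_classes))
  soft_labels(probs, coarse_spacing, gt$origin)
}

#' Fine hard targets from ground-truth labels
#'
#' Nearest-neighbour interpolation of the label map to the fine-stage spacing.
#'
#' @param gt a `cbct_labels`.
#' @param fine_spacing target spacing in mm (scalar isotropic or length 3).
#' @return a `cbct_labels` at `fine_spacing`.
#' @export
make_fine_targets <- function(gt, fine_spacing = 0.25) {
  stopifnot(inherits(gt, "cbct_labels"))
  if (length(fine_spacing) == 1L) fine_spacing <- rep(fine_spacing, 3L)
  resample(gt, fine_spacing)
}

# resample a (x,y,z,C) probability array channelwise with trilinear
# interpolation, then clip and renormalize to absorb float drift
resample_probs <- function(probs, spacing, target_spacing) {
  C <- dim(probs)[4]
  ch <- lapply(seq_len(C), function(c)
    resample_array(probs[, , , c], spacing, target_spacing, "linear"))
  out <- array(unlist(ch, use.names = FALSE), c(dim(ch[[1]]), C))
  out <- pmax(out, 0)
  s <- array(rowSums(matrix(out, ncol = C)), dim(out)[1:3])
  sweep_div <- as.vector(out) / rep(as.vector(s), times = C)
  array(sweep_div, dim(out))
}
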