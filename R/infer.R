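#' Plan overlapping tiles over a volume
#'
#' Tiles of edge `patch_size` with stride `patch_size - overlap` per axis; the
#' last tile on each axis is shifted inward to end exactly at the boundary, so
#' every voxel is covered at least once. Volumes smaller than the patch are
#' padded (the plan records the padded shape).
#'
#' @param shape voxel triple of the volume to tile.
#' @param patch_size cubic patch edge (or length-3) in voxels.
#' @param overlap minimum tile overlap per axis, voxels (< patch_size).
#' @return a `cbct_tiling_plan`: `origins` (matrix, 1-based), `patch_size`,
#'   `overlap`, `padded_shape`, `shape`.
#' @export
plan_tiles <- function(shape, patch_size, overlap = 16L) {
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  patch_size <- as.integer(patch_size); shape <- as.integer(shape)
  overlap <- as.integer(overlap)
  if (any(overlap >= patch_size)) stopf("overlap must be < patch_size")
  padded <- pmax(shape, patch_size)
  stride <- patch_size - overlap
  axis_origins <- function(n, p, s) {
    o <- seq.int(1L, by = s, length.out = max(1L, ceiling((n - p) / s) + 1L))
    o[o + p - 1L > n] <- n - p + 1L
    unique(o)
  }
  ox <- axis_origins(padded[1], patch_size[1], stride[1])
  oy <- axis_origins(padded[2], patch_size[2], stride[2])
  oz <- axis_origins(padded[3], patch_size[3], stride[3])
  origins <- as.matrix(expand.grid(x = ox, y = oy, z = oz))
  structure(list(origins = origins, patch_size = patch_size, overlap = overlap,
                 padded_shape = padded, shape = shape),
            class = "cbct_tiling_plan")
}

#' Centre-heavy aggregation weight map
#'
#' Separable product of per-axis Hann windows, floored at 1% of its maximum:
#' strictly positive, maximal at the patch centre, symmetric under axis
#' reflection, so centre voxels dominate the blended prediction.
#'
#' @param patch_size cubic patch edge (or length-3), >= 2 per axis.
#' @return a 3D array of positive weights.
#' @export
make_weight_map <- function(patch_size) {
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  stopifnot(all(patch_size >= 2))
  win <- function(n) sin(pi * (seq_len(n) - 0.5) / n)^2
  w <- outer(outer(win(patch_size[1]), win(patch_size[2])), win(patch_size[3]))
  w <- array(w, patch_size)
  pmax(w, 0.01 * max(w))
}

#' Aggregate overlapping patch predictions
#'
#' Blends per-patch class probabilities into a full volume: each voxel is the
#' weight-map-weighted average of all tiles covering it, then the result is
#' cropped back to the unpadded shape.
#'
#' @param patch_preds list of per-tile probability arrays `(px, py, pz, C)`
#'   (post-softmax), one per row of `plan$origins`, in order.
#' @param plan a [plan_tiles()] result.
#' @param w weight map from [make_weight_map()] (defaults to it).
#' @param spacing mm triple for the output.
#' @return a `cbct_soft_labels` over `plan$shape`.
#' @export
aggregate_patches <- function(patch_preds, plan, w = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(plan, "cbct_tiling_plan"))
  n <- nrow(plan$origins)
  if (length(patch_preds) != n)
    stopf("%d predictions for %d planned tiles", length(patch_preds), n)
  ps <- plan$patch_size
  w <- w %||% make_weight_map(ps)
  C <- dim(patch_preds[[1]])[4]
  pd <- plan$padded_shape
  num <- array(0, c(pd, C))
  den <- array(0, pd)
  for (t in seq_len(n)) {
    o <- plan$origins[t, ]
    i <- o[1]:(o[1] + ps[1] - 1L); j <- o[2]:(o[2] + ps[2] - 1L)
    k <- o[3]:(o[3] + ps[3] - 1L)
    den[i, j, k] <- den[i, j, k] + w
    for (c in seq_len(C))
      num[i, j, k, c] <- num[i, j, k, c] + w * patch_preds[[t]][, , , c]
  }
  probs <- num / as.vector(den) # den recycles over the channel dimension
  dim(probs) <- c(pd, C)
  s <- plan$shape
  probs <- probs[seq_len(s[1]), seq_len(s[2]), seq_len(s[3]), , drop = FALSE]
  soft_labels(probs, spacing)
}

#' Run the full two-stage segmentation pipeline on one volume
#'
#' normalize -> resample to coarse spacing -> single whole-volume coarse
#' forward pass -> interpolate probabilities to fine spacing -> concatenate
#' with the fine-resampled intensity -> tiled fine inference -> centre-weighted
#' aggregation -> per-voxel argmax (ties broken by the lowest class index).
#'
#' @param v a `cbct_volume` in acquisition intensity units.
#' @param coarse_ckpt,fine_ckpt `cbct_checkpoint`s of the two stages.
#' @param coarse_spacing,fine_spacing stage voxel spacings, mm.
#' @param patch_size,overlap fine-stage tiling geometry, voxels.
#' @param window intensity normalization window.
#' @param return_probs also return the aggregated fine probability field.
#' @return a `cbct_labels` at `fine_spacing` (plus `$probs` attribute when
#'   `return_probs`).
#' @export
predict_volume <- function(v, coarse_ckpt, fine_ckpt,
                           coarse_spacing = 1.0, fine_spacing = 0.25,
                           patch_size = 144L, overlap = 16L,
                           window = c(-1000, 2000), return_probs = FALSE) {
  stopifnot(inherits(v, "cbct_volume"))
  if (length(coarse_spacing) == 1L) coarse_spacing <- rep(coarse_spacing, 3L)
  if (length(fine_spacing) == 1L) fine_spacing <- rep(fine_spacing, 3L)
  nv <- normalize_intensity(v, window)
  coarse_in <- resample(nv, coarse_spacing, "linear")
  cprobs <- .coarse_probs(coarse_ckpt, coarse_in$data)
  hint <- resample_probs(cprobs, coarse_spacing, fine_spacing)
  fine_img <- resample(nv, fine_spacing, "linear")
  d <- dim(fine_img$data)
  dh <- dim(hint)[1:3]
  # ceil-based shapes from the two resample paths can differ by one voxel
  dc <- pmin(d, dh)
  x <- concat_hint(
    volume(fine_img$data[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE],
           fine_spacing),
    soft_labels(hint[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), , drop = FALSE],
                fine_spacing))
  plan <- plan_tiles(dc, patch_size, overlap)
  pad <- plan$padded_shape
  x <- pad_to(x, pad, fill = 0)
  x <- .pad_hint_background(x, dc)
  wmap <- make_weight_map(plan$patch_size)
  C <- fine_ckpt$model$config$num_classes
  preds <- vector("list", nrow(plan$origins))
  for (t in seq_len(nrow(plan$origins))) {
    patch <- extract_patch(x, plan$origins[t, ], plan$patch_size[1])
    sc <- unet_forward(fine_ckpt$model, patch, plan$patch_size)$scores
    preds[[t]] <- array(softmax_rows(sc), c(plan$patch_size, C))
  }
  agg <- aggregate_patches(preds, plan, wmap, spacing = fine_spacing)
  lab <- argmax_rows(matrix(agg$probs, ncol = C)) - 1L
  out <- label_volume(array(lab, dim(agg$probs)[1:3]), C, fine_spacing, v$origin)
  if (return_probs) attr(out, "probs") <- agg
  out
}

# padded hint voxels carry no probability mass; make them background one-hot
.pad_hint_background <- function(x, orig_dims) {
  d <- dim(x)[1:3]
  if (all(d == orig_dims)) return(x)
  mask <- array(TRUE, d)
  mask[seq_len(orig_dims[1]), seq_len(orig_dims[2]), seq_len(orig_dims[3])] <- FALSE
  bg <- x[, , , 2]
  bg[mask] <- 1
  x[, , , 2] <- bg
  x
}

#' Dice overlap coefficient between two masks
#' @param a,b logical/0-1 arrays of identical shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
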