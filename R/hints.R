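#' Balanced k-fold assignment of subjects
#'
#' @param ids subject ids (length >= k).
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @return a named integer vector mapping id -> fold in `0:(k-1)`; fold sizes
#'   differ by at most 1.
#' @export
kfold_split <- function(ids, k = 3L, seed = 1L) {
  n <- length(ids)
  if (n < k) stopf("need at least k = %d ids, got %d", k, n)
  perm <- with_seed(seed, sample(ids))
  fold <- rep(seq_len(k) - 1L, length.out = n)
  out <- fold[order(match(ids, perm))]
  names(out) <- ids
  out
}

# pad a 3D array to dims divisible by 2^(depth-1) (and >= lo), run the coarse
# model on the whole volume, softmax, crop back; returns (x,y,z,C) probs
.coarse_probs <- function(ckpt, input3d) {
  model <- ckpt$model
  div <- 2L^(model$config$depth - 1L)
  d <- dim(input3d)
  td <- round_up(d, div)
  x <- pad_to(input3d, td, fill = 0)
  sc <- unet_forward(model, x, td)$scores
  p <- softmax_rows(sc)
  probs <- array(p, c(td, ncol(p)))
  probs[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , drop = FALSE]
}

#' Generate leakage-free coarse hints
#'
#' For every cross-validated training subject, the hint is predicted by the
#' fold model that never saw that subject, then linearly interpolated
#' channelwise to the fine spacing, clipped to `[0, 1]` and renormalized.
#' Subjects absent from `assignment` (dev/test/inference subjects) get their
#' hint from `full_ckpt`, the coarse model trained on all training data.
#'
#' @param inputs named list (by subject id) of normalized coarse-spacing
#'   intensity arrays (3D).
#' @param assignment a [kfold_split()] result over the training ids.
#' @param fold_ckpts list of `cbct_checkpoint`s, one per fold; fold f's model
#'   must have been trained only on ids outside fold f (audited here).
#' @param full_ckpt coarse checkpoint trained on all training data.
#' @param coarse_spacing,fine_spacing mm (scalars or length 3).
#' @return named list of `cbct_soft_labels` hints at `fine_spacing`.
#' @export
generate_hints <- function(inputs, assignment, fold_ckpts, full_ckpt,
                           coarse_spacing = 1.0, fine_spacing = 0.25) {
  if (length(coarse_spacing) == 1L) coarse_spacing <- rep(coarse_spacing, 3L)
  if (length(fine_spacing) == 1L) fine_spacing <- rep(fine_spacing, 3L)
  out <- list()
  for (id in names(inputs)) {
    if (id %in% names(assignment)) {
      f <- assignment[[id]]
      if (f + 1L > length(fold_ckpts)) stopf("missing fold model %d for %s", f, id)
      ck <- fold_ckpts[[f + 1L]]
      if (id %in% ck$train_ids)
        stopf("data leakage: fold %d model for subject %s was trained on it", f, id)
    } else {
      ck <- full_ckpt
    }
    probs <- .coarse_probs(ck, inputs[[id]])
    fine <- resample_probs(probs, coarse_spacing, fine_spacing)
    out[[id]] <- soft_labels(fine, fine_spacing)
  }
  out
}

#' Assemble the fine-stage input channels
#'
#' Channel 1 is the normalized intensity at fine spacing; channels 2..C+1 are
#' the coarse-hint class probabilities in fixed class order.
#'
#' @param image a `cbct_volume` at fine spacing (normalized intensities).
#' @param hint a `cbct_soft_labels` with the same spatial shape and spacing.
#' @return a 4D `(x, y, z, C+1)` array.
#' @export
concat_hint <- function(image, hint) {
  stopifnot(inherits(image, "cbct_volume"), inherits(hint, "cbct_soft_labels"))
  di <- dim(image$data); dh <- dim(hint$probs)
  if (!all(di == dh[1:3]))
    stopf("image (%s) and hint (%s) shapes differ",
          paste(di, collapse = "x"), paste(dh[1:3], collapse = "x"))
  if (max(abs(image$spacing - hint$spacing)) > 1e-6)
    stopf("image and hint spacings differ")
  array(c(image$data, hint$probs), c(di, dh[4] + 1L))
}
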