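# End-to-end orchestration of the cascade: preprocessing, coarse training
# (full + k-fold for hints), hint generation, fine training, inference.

#' Pipeline settings
#'
#' Stage spacings default to the full-scale recipe (1.0 mm coarse, 0.25 mm
#' fine); desk-scale runs use 2.0 / 1.0 mm.
#'
#' @param coarse_spacing,fine_spacing stage voxel spacings, mm.
#' @param window intensity normalization window.
#' @param num_classes class count C.
#' @param base_channels,depth U-Net size (shared by both stages).
#' @param patch_size,overlap fine-stage patch edge and inference overlap.
#' @param k_folds folds for leakage-free hint generation.
#' @return a `cbct_pipeline_config` list.
#' @export
pipeline_config <- function(coarse_spacing = 1.0, fine_spacing = 0.25,
                            window = c(-1000, 2000), num_classes = 6L,
                            base_channels = 32L, depth = 4L,
                            patch_size = 144L, overlap = 16L, k_folds = 3L) {
  structure(list(coarse_spacing = coarse_spacing, fine_spacing = fine_spacing,
                 window = window, num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), patch_size = as.integer(patch_size),
                 overlap = as.integer(overlap), k_folds = as.integer(k_folds)),
            class = "cbct_pipeline_config")
}

# normalized intensity at coarse spacing + soft target, for one subject
prepare_coarse_sample <- function(id, vol, labels, pcfg) {
  nv <- normalize_intensity(vol, pcfg$window)
  ci <- resample(nv, pcfg$coarse_spacing, "linear")
  st <- make_soft_targets(labels, pcfg$coarse_spacing)
  dt <- pmin(dim(ci$data), dim(st$probs)[1:3])
  list(id = id,
       input = ci$data[seq_len(dt[1]), seq_len(dt[2]), seq_len(dt[3]), drop = FALSE],
       target = st$probs[seq_len(dt[1]), seq_len(dt[2]), seq_len(dt[3]), , drop = FALSE])
}

# intensity + hint channels at fine spacing + hard target, for one subject
prepare_fine_sample <- function(id, vol, labels, hint, pcfg) {
  nv <- normalize_intensity(vol, pcfg$window)
  fi <- resample(nv, pcfg$fine_spacing, "linear")
  ft <- make_fine_targets(labels, pcfg$fine_spacing)
  dt <- pmin(dim(fi$data), dim(hint$probs)[1:3], dim(ft$labels))
  img <- volume(fi$data[seq_len(dt[1]), seq_len(dt[2]), seq_len(dt[3]), drop = FALSE],
                rep(pcfg$fine_spacing, length.out = 3))
  hp <- soft_labels(hint$probs[seq_len(dt[1]), seq_len(dt[2]), seq_len(dt[3]), , drop = FALSE],
                    img$spacing)
  list(id = id, input = concat_hint(img, hp),
       target = ft$labels[seq_len(dt[1]), seq_len(dt[2]), seq_len(dt[3]), drop = FALSE])
}

#' Train the full two-stage cascade on a cohort
#'
#' Splits the cohort 90/5/5, trains the coarse model on all training subjects
#' (soft targets) plus one coarse model per fold for leakage-free hints,
#' interpolates out-of-fold coarse predictions to the fine spacing, and trains
#' the fine model on intensity + hint channels against hard labels.
#'
#' @param subjects named list, each `list(volume = cbct_volume,
#'   labels = cbct_labels)` (e.g. from [generate_phantom_cohort()]).
#' @param pcfg a [pipeline_config()].
#' @param coarse_cfg,fine_cfg [train_config()]s for the two stages.
#' @param seed master seed (splits, folds, weights).
#' @param verbose print per-epoch losses.
#' @return a `cbct_pipeline_fit`: checkpoints, split, fold assignment.
#' @export
train_pipeline <- function(subjects, pcfg, coarse_cfg, fine_cfg, seed = 1L,
                           verbose = FALSE) {
  ids <- names(subjects)
  split <- split_dataset(ids, coarse_cfg$split_fracs, seed = seed)

  coarse_samples <- lapply(ids, function(id)
    prepare_coarse_sample(id, subjects[[id]]$volume, subjects[[id]]$labels, pcfg))
  names(coarse_samples) <- ids
  pick <- function(set) unname(coarse_samples[set])

  new_coarse <- function(s) build_model(
    model_config("coarse", pcfg$num_classes, pcfg$base_channels, pcfg$depth),
    seed = s)

  # full-data coarse model: hints for dev/test/inference subjects
  coarse_full <- train_stage(list(train = pick(split$train), dev = pick(split$dev)),
                             coarse_cfg, new_coarse(seed), verbose = verbose)

  # per-fold coarse models: out-of-fold hints for the training subjects
  assignment <- kfold_split(split$train, k = pcfg$k_folds, seed = seed + 1L)
  fold_ckpts <- lapply(seq_len(pcfg$k_folds) - 1L, function(f) {
    in_fold <- names(assignment)[assignment == f]
    train_stage(list(train = pick(setdiff(split$train, in_fold)),
                     dev = pick(split$dev)),
                coarse_cfg, new_coarse(seed + 10L + f), verbose = verbose)
  })

  hint_inputs <- lapply(coarse_samples, `[[`, "input")
  hints <- generate_hints(hint_inputs, assignment, fold_ckpts, coarse_full,
                          pcfg$coarse_spacing, pcfg$fine_spacing)

  fine_samples <- lapply(ids, function(id)
    prepare_fine_sample(id, subjects[[id]]$volume, subjects[[id]]$labels,
                        hints[[id]], pcfg))
  names(fine_samples) <- ids
  fine_ckpt <- train_stage(list(train = unname(fine_samples[split$train]),
                                dev = unname(fine_samples[split$dev])),
                           fine_cfg,
                           build_model(model_config("fine", pcfg$num_classes,
                                                    pcfg$base_channels, pcfg$depth),
                                       seed = seed + 2L),
                           verbose = verbose)

  structure(list(coarse = coarse_full, folds = fold_ckpts, fine = fine_ckpt,
                 split = split, assignment = assignment, config = pcfg),
            class = "cbct_pipeline_fit")
}

#' @export
print.cbct_pipeline_fit <- function(x, ...) {
  cat(sprintf("<cbct_pipeline_fit> %d train / %d dev / %d test subjects, %d hint folds\n",
              length(x$split$train), length(x$split$dev), length(x$split$test),
              length(x$folds)))
  print(x$coarse); print(x$fine)
  invisible(x)
}

#' Segment a volume with a fitted cascade
#'
#' @param fit a `cbct_pipeline_fit`.
#' @param vol a `cbct_volume` in acquisition units.
#' @param ... passed to [predict_volume()].
#' @return a `cbct_labels` at the fine spacing.
#' @export
segment_volume <- function(fit, vol, ...) {
  p <- fit$config
  predict_volume(vol, fit$coarse, fit$fine,
                 coarse_spacing = p$coarse_spacing, fine_spacing = p$fine_spacing,
                 patch_size = p$patch_size, overlap = p$overlap,
                 window = p$window, ...)
}

#' Evaluate a fitted cascade on held-out subjects
#'
#' @param fit a `cbct_pipeline_fit`.
#' @param subjects the cohort used for [train_pipeline()].
#' @param ids subjects to evaluate (default: the test split).
#' @param bounds optional [airway_bounds()] delimiting the measured airway
#'   segment (the analogue of the landmark planes used on real scans); without
#'   bounds the ragged ends of a predicted airway can dominate the minimum
#'   cross-sectional area.
#' @return data.frame with per-class Dice and airway metrics per subject.
#' @export
evaluate_pipeline <- function(fit, subjects, ids = fit$split$test,
                              bounds = NULL) {
  p <- fit$config
  rows <- lapply(ids, function(id) {
    s <- subjects[[id]]
    pred <- segment_volume(fit, s$volume)
    truth <- make_fine_targets(s$labels, p$fine_spacing)
    dt <- pmin(dim(pred$labels), dim(truth$labels))
    pl <- pred$labels[seq_len(dt[1]), seq_len(dt[2]), seq_len(dt[3])]
    tl <- truth$labels[seq_len(dt[1]), seq_len(dt[2]), seq_len(dt[3])]
    dice <- vapply(seq_len(p$num_classes) - 1L,
                   function(c) dice_coefficient(pl == c, tl == c), numeric(1))
    m <- tryCatch(
      airway_metrics(label_volume(pl, p$num_classes,
                                  rep(p$fine_spacing, length.out = 3)), bounds),
      error = function(e) list(volume_cc = 0, min_csa_mm2 = NA_real_,
                               narrowest_mm = NA_real_, narrow_slice_z = NA_real_))
    data.frame(id = id, t(setNames(dice, paste0("dice_", class_names()))),
               volume_cc = m$volume_cc, min_csa_mm2 = m$min_csa_mm2,
               narrowest_mm = m$narrowest_mm, narrow_slice_z = m$narrow_slice_z)
  })
  do.call(rbind, rows)
}
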