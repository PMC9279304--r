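#' Training configuration
#'
#' Defaults follow the full-scale training recipe: Adam with a one-cycle
#' learning-rate policy (max 1e-3, min 1e-6, warmup fraction 0.05), batch
#' size 1, 144^3 fine-stage patches sampled 20 per volume into a queue of
#' capacity 180, and a 90/5/5 train/dev/test split. Desk-scale runs override
#' `epochs`, `patch_size` and `samples_per_volume`.
#'
#' @param epochs training epochs (100 for the coarse stage, 40 for the fine
#'   stage at full scale).
#' @param max_lr,min_lr one-cycle learning-rate extremes.
#' @param warmup_frac fraction of total steps spent ramping up to `max_lr`.
#' @param batch_size samples per optimizer step (1).
#' @param patch_size fine-stage cubic patch edge, voxels.
#' @param samples_per_volume patches sampled per volume per epoch.
#' @param queue_capacity maximum patch-queue occupancy.
#' @param seed integer RNG seed for all training randomness.
#' @param split_fracs train/dev/test fractions summing to 1.
#' @param augment an [augment_params()] list, or `NULL` for no augmentation.
#' @return a `cbct_train_config` list.
#' @export
train_config <- function(epochs = 100L, max_lr = 1e-3, min_lr = 1e-6,
                         warmup_frac = 0.05, batch_size = 1L,
                         patch_size = 144L, samples_per_volume = 20L,
                         queue_capacity = 180L, seed = 1L,
                         split_fracs = c(0.90, 0.05, 0.05),
                         augment = NULL) {
  stopifnot(warmup_frac > 0, warmup_frac < 1, min_lr < max_lr,
            queue_capacity >= samples_per_volume,
            abs(sum(split_fracs) - 1) < 1e-9)
  structure(list(epochs = as.integer(epochs), max_lr = max_lr, min_lr = min_lr,
                 warmup_frac = warmup_frac, batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 samples_per_volume = as.integer(samples_per_volume),
                 queue_capacity = as.integer(queue_capacity),
                 seed = as.integer(seed), split_fracs = split_fracs,
                 augment = augment),
            class = "cbct_train_config")
}

#' Split subject ids into train/dev/test sets
#'
#' Sizes are the rounded fractions with the remainder assigned to the training
#' split; dev and test always receive at least one subject. The partition is
#' disjoint, exhaustive and reproducible from `seed`.
#'
#' @param ids character or integer subject ids (>= 3).
#' @param fracs length-3 fractions summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `dev`, `test`.
#' @export
split_dataset <- function(ids, fracs = c(0.90, 0.05, 0.05), seed = 1L) {
  n <- length(ids)
  if (n < 3L) stopf("need at least 3 ids to populate train/dev/test, got %d", n)
  if (abs(sum(fracs) - 1) > 1e-9) stopf("fracs must sum to 1")
  n_dev <- max(1L, as.integer(round(fracs[2] * n)))
  n_test <- max(1L, as.integer(round(fracs[3] * n)))
  if (n_dev + n_test >= n) stopf("too few ids for the requested fractions")
  perm <- with_seed(seed, sample(ids))
  list(train = perm[seq_len(n - n_dev - n_test)],
       dev = perm[seq(n - n_dev - n_test + 1L, n - n_test)],
       test = perm[seq(n - n_test + 1L, n)])
}

#' One-cycle learning-rate schedule
#'
#' Linear warmup from `min_lr` to `max_lr` over the first
#' `round(warmup_frac * total_steps)` steps, then cosine annealing back to
#' `min_lr` at the final step. Continuous and unimodal in `step`.
#'
#' @param step 0-based step index, `0 <= step < total_steps`.
#' @param total_steps total optimizer steps (>= 2).
#' @param max_lr,min_lr,warmup_frac schedule parameters.
#' @return the learning rate at `step`.
#' @export
one_cycle_lr <- function(step, total_steps, max_lr = 1e-3, min_lr = 1e-6,
                         warmup_frac = 0.05) {
  if (total_steps < 2L) stopf("total_steps must be >= 2")
  if (any(step < 0 | step >= total_steps)) stopf("step out of range")
  w <- round(warmup_frac * total_steps)
  lr <- numeric(length(step))
  up <- step <= w
  if (w > 0) lr[up] <- min_lr + (max_lr - min_lr) * step[up] / w
  else lr[up] <- max_lr
  t <- (step[!up] - w) / (total_steps - 1 - w)
  lr[!up] <- min_lr + (max_lr - min_lr) * (1 + cos(pi * t)) / 2
  lr
}

# ---- loss -----------------------------------------------------------------

# coerce a target to a V x C probability matrix
.target_matrix <- function(target, C, V) {
  if (inherits(target, "cbct_soft_labels")) target <- target$probs
  if (inherits(target, "cbct_labels")) target <- target$labels
  if (is.array(target) && length(dim(target)) == 4L)
    return(matrix(target, ncol = dim(target)[4]))
  if (is.matrix(target) && ncol(target) == C) return(target)
  # integer labels (vector or 3D array)
  lab <- as.integer(target)
  if (any(lab < 0L | lab > C - 1L)) stopf("target class out of range [0, %d]", C - 1L)
  g <- matrix(0, length(lab), C)
  g[cbind(seq_along(lab), lab + 1L)] <- 1
  g
}

#' Combined cross-entropy + soft multiclass Jaccard loss
#'
#' `loss = CE + (1 - mean_c J_c)` where, for class c with predicted
#' probabilities `p = softmax(scores)` and target probabilities `g`,
#' `J_c = (sum(p_c g_c) + eps) / (sum(p_c) + sum(g_c) - sum(p_c g_c) + eps)`
#' and `CE = -mean_v sum_c g_c log p_c`. Targets may be hard labels
#' (`cbct_labels`, integer array/vector) or soft distributions
#' (`cbct_soft_labels`, `V x C` matrix, 4D array); hard labels are treated as
#' one-hot distributions, so both target kinds share one formula.
#'
#' @param scores `V x C` score (logit) matrix.
#' @param target hard or soft target (see above).
#' @param eps Jaccard smoothing constant.
#' @param grad if `TRUE`, also return `dscores`, the loss gradient.
#' @return list with `loss`, `ce`, `jaccard` (the mean soft Jaccard index)
#'   and optionally `dscores`.
#' @export
combined_loss <- function(scores, target, eps = 1e-6, grad = FALSE) {
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = dim(scores)[length(dim(scores))])
  if (any(!is.finite(scores))) stopf("non-finite scores in loss")
  C <- ncol(scores); V <- nrow(scores)
  g <- .target_matrix(target, C, V)
  if (nrow(g) != V) stopf("target shape does not match scores")
  p <- softmax_rows(scores)
  logp <- log(pmax(p, 1e-300))
  ce <- -sum(g * logp) / V
  num <- colSums(p * g) + eps
  den <- colSums(p) + colSums(g) - colSums(p * g) + eps
  jac <- num / den
  loss <- ce + (1 - mean(jac))
  out <- list(loss = loss, ce = ce, jaccard = mean(jac))
  if (grad) {
    dce <- (p - g) / V
    # d/dp of -(1/C) sum_c J_c: per class, (g*den - num*(1-g)) / den^2
    djac_dp <- -(sweep(g, 2L, den, "*") - sweep(1 - g, 2L, num, "*")) /
      matrix(den^2, V, C, byrow = TRUE) / C
    # softmax chain rule
    srow <- rowSums(djac_dp * p)
    djac_dz <- p * (djac_dp - srow)
    out$dscores <- dce + djac_dz
  }
  out
}

# ---- optimizer ------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- patch queue ----------------------------------------------------------

#' Sample training patches through a bounded shuffled queue
#'
#' Iterates over the volumes in random order, samples `samples_per_volume`
#' random patch origins per volume into a queue, and emits patches in random
#' order whenever occupancy reaches `queue_capacity`, flushing the remainder
#' at the end of the epoch. Returns patch descriptors (volume index + 1-based
#' origin), not pixel data; use [extract_patch()] to materialize one.
#'
#' @param vol_dims list of spatial dims `(nx, ny, nz)` per volume (each >=
#'   `patch_size` after padding).
#' @param cfg a [train_config()] (uses `patch_size`, `samples_per_volume`,
#'   `queue_capacity`).
#' @param seed integer seed for this epoch's sampling.
#' @return list with `patches` (list of `list(vol, origin)` in emission
#'   order) and `max_occupancy`.
#' @export
patch_queue <- function(vol_dims, cfg, seed = 1L) {
  stopifnot(length(vol_dims) >= 1L)
  ps <- cfg$patch_size
  with_seed(seed, {
    queue <- vector("list", cfg$queue_capacity)
    qn <- 0L
    emitted <- list()
    max_occ <- 0L
    pop_random <- function() {
      i <- sample.int(qn, 1L)
      el <- queue[[i]]
      queue[[i]] <<- queue[[qn]]
      qn <<- qn - 1L
      el
    }
    for (v in sample(seq_along(vol_dims))) {
      d <- vol_dims[[v]]
      if (any(d < ps)) stopf("volume %d (%s) smaller than patch %d; pad first",
                             v, paste(d, collapse = "x"), ps)
      for (s in seq_len(cfg$samples_per_volume)) {
        org <- vapply(1:3, function(a) sample.int(d[a] - ps + 1L, 1L), integer(1))
        qn <- qn + 1L
        queue[[qn]] <- list(vol = v, origin = org)
        max_occ <- max(max_occ, qn)
        while (qn >= cfg$queue_capacity) emitted[[length(emitted) + 1L]] <- pop_random()
      }
    }
    while (qn > 0L) emitted[[length(emitted) + 1L]] <- pop_random()
    list(patches = emitted, max_occupancy = max_occ)
  })
}

#' Extract a cubic patch from a 3D or 4D (channels-last) array
#' @param x array; @param origin 1-based corner; @param size patch edge.
#' @return the patch, same number of dimensions as `x`.
#' @export
extract_patch <- function(x, origin, size) {
  i <- origin[1]:(origin[1] + size - 1L)
  j <- origin[2]:(origin[2] + size - 1L)
  k <- origin[3]:(origin[3] + size - 1L)
  if (length(dim(x)) == 4L) x[i, j, k, , drop = FALSE] else x[i, j, k, drop = FALSE]
}

# pad a 3D/4D array on the high side to target spatial dims; image channels
# pad with `fill`, probability channel 1 (background) of a target pads with 1
pad_to <- function(x, target, fill = 0, background_channel = NA) {
  d <- dim(x)
  nd <- length(d)
  td <- c(as.integer(target), if (nd == 4L) d[4])
  if (all(d == td)) return(x)
  out <- array(fill, td)
  if (!is.na(background_channel)) {
    out[, , , background_channel] <- 1
  }
  if (nd == 4L) out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
  else out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

# next multiple of m, at least lo
round_up <- function(n, m, lo = 0L) pmax(as.integer(ceiling(n / m) * m), lo)

# ---- stage training loop --------------------------------------------------

#' Train one stage (coarse or fine) of the cascade
#'
#' Coarse stage: batch size 1 means one whole volume per optimizer step,
#' trained against soft targets. Fine stage: one patch per step, drawn through
#' the shuffled bounded queue, trained against hard labels. Returns the
#' parameter snapshot with the lowest recorded dev loss.
#'
#' @param dataset list with `train` and `dev`: each a list of samples
#'   `list(id, input, target)` where `input` is a 3D intensity array (coarse)
#'   or 4D intensity+hint array (fine), and `target` a 4D soft-target array
#'   (coarse) or integer label array (fine).
#' @param cfg a [train_config()].
#' @param model a freshly built [build_model()] of the matching stage.
#' @param verbose print per-epoch losses.
#' @return a `cbct_checkpoint`: best model, training log, config, train ids.
#' @export
train_stage <- function(dataset, cfg, model, verbose = FALSE) {
  stopifnot(inherits(cfg, "cbct_train_config"), inherits(model, "cbct_unet3d"))
  stage <- model$config$stage
  div <- 2L^(model$config$depth - 1L)
  n_train <- length(dataset$train)
  if (n_train < 1L || length(dataset$dev) < 1L)
    stopf("dataset needs nonempty train and dev splits")

  prep <- function(s) {
    d <- dim(s$input)[1:3]
    td <- round_up(d, div, lo = if (stage == "fine") cfg$patch_size else 0L)
    s$input <- pad_to(s$input, td, fill = 0)
    s$target <- if (length(dim(s$target)) == 4L)
      pad_to(s$target, td, fill = 0, background_channel = 1L)
    else pad_to(s$target, td, fill = 0L)
    s
  }
  train_set <- lapply(dataset$train, prep)
  dev_set <- lapply(dataset$dev, prep)

  steps_per_epoch <- if (stage == "coarse") n_train
                     else n_train * cfg$samples_per_volume
  total_steps <- cfg$epochs * steps_per_epoch
  opt <- adam_init(model$params)
  step <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    dev_loss = numeric(), lr = numeric())
  best <- list(loss = Inf, params = model$params, epoch = 0L)

  eval_loss <- function(params) {
    m <- model; m$params <- params
    mean(vapply(dev_set, function(s) {
      sc <- unet_forward(m, s$input, dim(s$input)[1:3])$scores
      combined_loss(sc, s$target)$loss
    }, numeric(1)))
  }

  one_step <- function(input, target) {
    dims <- dim(input)[1:3]
    fw <- unet_forward(model, input, dims, train = TRUE)
    ls <- combined_loss(fw$scores, target, grad = TRUE)
    if (!is.finite(ls$loss))
      stopf("non-finite training loss at step %d (stage %s)", step, stage)
    grads <- unet_backward(model, ls$dscores, fw$cache)
    lr <- one_cycle_lr(step, total_steps, cfg$max_lr, cfg$min_lr, cfg$warmup_frac)
    upd <- adam_step(model$params, grads, opt, lr)
    model$params <<- upd$params
    opt <<- upd$state
    step <<- step + 1L
    ls$loss
  }

  for (epoch in seq_len(cfg$epochs)) {
    ep_seed <- (cfg$seed + 7919L * epoch) %% .Machine$integer.max
    losses <- numeric(0)
    if (stage == "coarse") {
      ord <- with_seed(ep_seed, sample(n_train))
      for (i in ord) {
        s <- train_set[[i]]
        if (!is.null(cfg$augment)) {
          a <- with_seed(ep_seed + i, augment(s$input, s$target, stage, cfg$augment))
          s$input <- a$image; s$target <- a$target
        }
        losses <- c(losses, one_step(s$input, s$target))
      }
    } else {
      q <- patch_queue(lapply(train_set, function(s) dim(s$input)[1:3]),
                       cfg, seed = ep_seed)
      for (pd in q$patches) {
        s <- train_set[[pd$vol]]
        inp <- extract_patch(s$input, pd$origin, cfg$patch_size)
        tgt <- extract_patch(s$target, pd$origin, cfg$patch_size)
        if (!is.null(cfg$augment)) {
          a <- with_seed(ep_seed + pd$vol * 1000L + step %% 1000L,
                         augment(inp, tgt, stage, cfg$augment))
          inp <- a$image; tgt <- a$target
        }
        losses <- c(losses, one_step(inp, tgt))
      }
    }
    lr_now <- one_cycle_lr(step - 1L, total_steps, cfg$max_lr, cfg$min_lr,
                           cfg$warmup_frac)
    dl <- eval_loss(model$params)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                 dev_loss = dl, lr = lr_now))
    if (dl < best$loss) best <- list(loss = dl, params = model$params, epoch = epoch)
    if (verbose)
      message(sprintf("[%s] epoch %d/%d train %.4f dev %.4f lr %.2e",
                      stage, epoch, cfg$epochs, mean(losses), dl, lr_now))
  }
  model$params <- best$params
  structure(list(model = model, best_epoch = best$epoch, best_dev_loss = best$loss,
                 log = log, config = cfg,
                 train_ids = vapply(dataset$train, function(s) as.character(s$id),
                                    character(1))),
            class = "cbct_checkpoint")
}

#' @export
print.cbct_checkpoint <- function(x, ...) {
  cat(sprintf("<cbct_checkpoint> stage=%s best epoch %d/%d (dev loss %.4f), %d training subjects\n",
              x$model$config$stage, x$best_epoch, nrow(x$log), x$best_dev_loss,
              length(x$train_ids)))
  invisible(x)
}

#' Save / load a training checkpoint
#' @param ckpt a `cbct_checkpoint`. @param path file path (.rds).
#' @return `path` / the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "cbct_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "cbct_checkpoint"))
  ckpt
}
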