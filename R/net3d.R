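# 3D U-Net, implemented directly on V x C feature matrices (V = nx*ny*nz
# voxels in column-major x-fastest order). Convolutions are im2col (C++) +
# BLAS GEMM; backward passes are hand-derived and checked against
# finite differences in the test suite.
#
# Architecture per encoder level: [conv3 -> instance norm -> ReLU] x 2,
# 2x max-pool between levels; decoder: nearest-neighbour 2x upsample,
# skip concatenation, then the same double-conv block; final 1x1 conv to
# class scores. Channel widths double per level from `base_channels`.

#' Model configuration for a segmentation stage
#'
#' The coarse stage consumes the intensity channel only (`in_channels = 1`);
#' the fine stage consumes intensity plus the C coarse-hint probability
#' channels (`in_channels = num_classes + 1`).
#'
#' @param stage `"coarse"` or `"fine"`.
#' @param num_classes number of output classes C (default 6).
#' @param base_channels width of the first encoder level (doubles per level).
#' @param depth number of encoder levels including the bottleneck (>= 2).
#'   Input spatial dimensions must be divisible by `2^(depth - 1)`.
#' @param in_channels input channels; defaults to the stage rule and is
#'   validated against it.
#' @return a `cbct_model_config` list.
#' @export
model_config <- function(stage = c("coarse", "fine"), num_classes = 6L,
                         base_channels = 16L, depth = 3L,
                         in_channels = NULL) {
  stage <- match.arg(stage)
  expected <- if (stage == "coarse") 1L else num_classes + 1L
  in_channels <- as.integer(in_channels %||% expected)
  if (in_channels != expected)
    stopf("%s stage requires in_channels = %d, got %d", stage, expected, in_channels)
  if (depth < 2L) stopf("depth must be >= 2")
  structure(list(stage = stage, num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), in_channels = in_channels,
                 norm = "instance", activation = "relu"),
            class = "cbct_model_config")
}

.level_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)

#' Build a 3D U-Net
#'
#' Initializes parameters (He-normal conv weights, unit-gain instance norm)
#' for the configured stage.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return a `cbct_unet3d` model (config + named parameter list).
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cbct_model_config"))
  ch <- .level_channels(cfg)
  params <- list()
  add_conv <- function(name, cin, cout, k = 3L) {
    fan_in <- cin * k^3
    params[[paste0(name, ".W")]] <<- matrix(
      rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_norm <- function(name, c) {
    params[[paste0(name, ".g")]] <<- rep(1, c)
    params[[paste0(name, ".be")]] <<- numeric(c)
  }
  with_seed(seed, {
    cin <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      add_conv(sprintf("enc%d.c1", l), cin, ch[l]); add_norm(sprintf("enc%d.n1", l), ch[l])
      add_conv(sprintf("enc%d.c2", l), ch[l], ch[l]); add_norm(sprintf("enc%d.n2", l), ch[l])
      cin <- ch[l]
    }
    for (l in rev(seq_len(cfg$depth - 1L))) {
      cat_in <- ch[l + 1L] + ch[l]
      add_conv(sprintf("dec%d.c1", l), cat_in, ch[l]); add_norm(sprintf("dec%d.n1", l), ch[l])
      add_conv(sprintf("dec%d.c2", l), ch[l], ch[l]); add_norm(sprintf("dec%d.n2", l), ch[l])
    }
    add_conv("out", ch[1], cfg$num_classes, k = 1L)
  })
  structure(list(config = cfg, params = params), class = "cbct_unet3d")
}

#' @export
print.cbct_unet3d <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<cbct_unet3d> stage=%s in=%d classes=%d base=%d depth=%d (%d parameters)\n",
              x$config$stage, x$config$in_channels, x$config$num_classes,
              x$config$base_channels, x$config$depth, np))
  invisible(x)
}

# ---- layer primitives -----------------------------------------------------

.conv_fwd <- function(x, dims, W, b, k = 3L) {
  if (k == 1L) return(sweep(x %*% W, 2L, b, "+"))
  conv3_fwd_cpp(x, as.integer(dims), W, b)
}

.conv_bwd <- function(dy, x, dims, W, k = 3L) {
  if (k == 1L)
    return(list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy)))
  conv3_bwd_cpp(dy, x, as.integer(dims), W)
}

.in_fwd <- function(x, g, be, eps = 1e-5) {
  mu <- colMeans(x)
  v <- colMeans(x * x) - mu^2
  istd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- scale_shift_cols_cpp(x, istd, -mu * istd)
  y <- scale_shift_cols_cpp(xhat, g, be)
  list(y = y, xhat = xhat, istd = istd)
}

.in_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  istd <- cache$istd
  dxhat <- scale_shift_cols_cpp(dy, g, numeric(length(g)))
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- add_scaled_cols_cpp(scale_shift_cols_cpp(dxhat, istd, -m1 * istd),
                            -m2 * istd, xhat)
  list(dx = dx, dg = colSums(dy * xhat), dbe = colSums(dy))
}

.block_fwd <- function(x, dims, params, prefix, cache = NULL) {
  keep <- !is.null(cache)
  for (i in 1:2) {
    cn <- sprintf("%s.c%d", prefix, i); nn <- sprintf("%s.n%d", prefix, i)
    xin <- x
    x <- .conv_fwd(x, dims, params[[paste0(cn, ".W")]], params[[paste0(cn, ".b")]])
    inr <- .in_fwd(x, params[[paste0(nn, ".g")]], params[[paste0(nn, ".be")]])
    y <- pmax(inr$y, 0)
    if (keep) cache[[paste0(prefix, i)]] <- list(xin = xin, inr = inr, mask = inr$y > 0)
    x <- y
  }
  if (keep) list(x = x, cache = cache) else x
}

.block_bwd <- function(dy, dims, params, prefix, cache, grads) {
  for (i in 2:1) {
    cn <- sprintf("%s.c%d", prefix, i); nn <- sprintf("%s.n%d", prefix, i)
    cc <- cache[[paste0(prefix, i)]]
    dy <- dy * cc$mask
    nb <- .in_bwd(dy, cc$inr, params[[paste0(nn, ".g")]])
    grads[[paste0(nn, ".g")]] <- nb$dg
    grads[[paste0(nn, ".be")]] <- nb$dbe
    cb <- .conv_bwd(nb$dx, cc$xin, dims, params[[paste0(cn, ".W")]])
    grads[[paste0(cn, ".W")]] <- cb$dW
    grads[[paste0(cn, ".b")]] <- cb$db
    dy <- cb$dx
  }
  list(dy = dy, grads = grads)
}

# ---- full network ---------------------------------------------------------

#' Forward pass of a 3D U-Net
#'
#' @param model a `cbct_unet3d`.
#' @param x input features, a `V x in_channels` matrix in column-major voxel
#'   order (x fastest), or a 3D/4D array which will be reshaped.
#' @param dims spatial dimensions `(nx, ny, nz)`; each must be divisible by
#'   `2^(depth - 1)`.
#' @param train if `TRUE`, also return the activation cache for [unet_backward()].
#' @return a list with `scores` (`V x C` matrix) and, when `train`, `cache`.
#' @export
unet_forward <- function(model, x, dims, train = FALSE) {
  cfg <- model$config; p <- model$params
  if (is.array(x) && length(dim(x)) >= 3L) {
    d <- dim(x)
    x <- matrix(x, nrow = prod(d[1:3]), ncol = if (length(d) == 4L) d[4] else 1L)
  }
  dims <- as.integer(dims)
  if (nrow(x) != prod(dims)) stopf("input rows != prod(dims)")
  if (ncol(x) != cfg$in_channels)
    stopf("input has %d channels, %s stage needs %d", ncol(x), cfg$stage, cfg$in_channels)
  div <- 2^(cfg$depth - 1L)
  if (any(dims %% div != 0))
    stopf("spatial dims (%s) must be divisible by %d for depth %d",
          paste(dims, collapse = "x"), div, cfg$depth)
  cache <- if (train) list(dims = list()) else NULL
  skips <- list(); skip_dims <- list()
  d <- dims
  for (l in seq_len(cfg$depth)) {
    pre <- sprintf("enc%d", l)
    if (train) {
      r <- .block_fwd(x, d, p, pre, cache); x <- r$x; cache <- r$cache
      cache$dims[[pre]] <- d
    } else x <- .block_fwd(x, d, p, pre)
    if (l < cfg$depth) {
      skips[[l]] <- x; skip_dims[[l]] <- d
      mp <- maxpool3(x, d)
      if (train) cache[[sprintf("pool%d", l)]] <- mp$argmax
      x <- mp$out; d <- mp$dims
    }
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    up <- upsample2_nn(x, d)
    d <- skip_dims[[l]]
    nch_up <- ncol(up)
    x <- cbind(up, skips[[l]])
    pre <- sprintf("dec%d", l)
    if (train) {
      cache[[sprintf("cat%d", l)]] <- nch_up
      r <- .block_fwd(x, d, p, pre, cache); x <- r$x; cache <- r$cache
      cache$dims[[pre]] <- d
    } else x <- .block_fwd(x, d, p, pre)
  }
  scores <- .conv_fwd(x, d, p[["out.W"]], p[["out.b"]], k = 1L)
  if (train) {
    cache$head_in <- x
    list(scores = scores, cache = cache)
  } else list(scores = scores)
}

#' Backward pass: parameter gradients from a score gradient
#'
#' @param model a `cbct_unet3d`.
#' @param dscores gradient of the loss with respect to the forward `scores`.
#' @param cache the cache returned by `unet_forward(..., train = TRUE)`.
#' @return named list of gradients matching `model$params`.
#' @export
unet_backward <- function(model, dscores, cache) {
  cfg <- model$config; p <- model$params
  grads <- list()
  hb <- .conv_bwd(dscores, cache$head_in, NULL, p[["out.W"]], k = 1L)
  grads[["out.W"]] <- hb$dW; grads[["out.b"]] <- hb$db
  dy <- hb$dx
  for (l in seq_len(cfg$depth - 1L)) {
    pre <- sprintf("dec%d", l)
    r <- .block_bwd(dy, cache$dims[[pre]], p, pre, cache, grads)
    grads <- r$grads
    nch_up <- cache[[sprintf("cat%d", l)]]
    dup <- r$dy[, seq_len(nch_up), drop = FALSE]
    # skip-path gradient is merged with the unpooled path in the encoder loop
    assign(sprintf("dskip%d", l), r$dy[, -seq_len(nch_up), drop = FALSE])
    dy <- upsample2_nn_bwd(dup, cache$dims[[pre]] %/% 2L)
  }
  # encoder backward, deepest level first
  for (l in rev(seq_len(cfg$depth))) {
    pre <- sprintf("enc%d", l)
    if (l < cfg$depth) {
      # unpool the gradient coming from below, add the skip gradient
      arg <- cache[[sprintf("pool%d", l)]]
      dfull <- matrix(0, prod(cache$dims[[pre]]), ncol(dy))
      for (c in seq_len(ncol(dy))) {
        dfull[arg[, c], c] <- dfull[arg[, c], c] + dy[, c]
      }
      dy <- dfull + get(sprintf("dskip%d", l))
    }
    r <- .block_bwd(dy, cache$dims[[pre]], p, pre, cache, grads)
    grads <- r$grads
    dy <- r$dy
  }
  grads
}

# numerically stable row-wise softmax of a V x C score matrix
softmax_rows <- function(scores) {
  e <- exp(scores - row_max_cpp(scores))
  e / rowSums(e)
}
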