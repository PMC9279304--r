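#' Augmentation parameters
#'
#' Probabilities and magnitudes of the training-time augmentations: random
#' blur, random noise, random rotations, random scaling, random crops, random
#' elastic deformation and random anisotropy. The fine stage never applies
#' elastic deformation or anisotropy (they are disabled there regardless of
#' these settings). Geometric transforms are applied identically to the image
#' (linear interpolation) and the target (nearest for hard labels, linear +
#' renormalization for soft targets).
#'
#' @param p_blur,blur_sd_max Gaussian blur probability and max sigma (voxels).
#' @param p_noise,noise_sd additive Gaussian noise probability and sd
#'   (normalized intensity units).
#' @param p_rotate,rotate_deg_max rotation probability and max |angle| about a
#'   random axis, degrees.
#' @param p_scale,scale_range uniform scaling probability and (lo, hi) factor.
#' @param p_crop,crop_frac random crop-and-pad probability and maximal cropped
#'   fraction per axis.
#' @param p_elastic,elastic_sd elastic-deformation probability and control
#'   point displacement sd (voxels); coarse stage only.
#' @param p_aniso,aniso_range anisotropic downsample-upsample probability and
#'   (lo, hi) downsampling factor; coarse stage only.
#' @return an `cbct_augment_params` list.
#' @export
augment_params <- function(p_blur = 0.2, blur_sd_max = 1.0,
                           p_noise = 0.2, noise_sd = 0.02,
                           p_rotate = 0.2, rotate_deg_max = 10,
                           p_scale = 0.2, scale_range = c(0.9, 1.1),
                           p_crop = 0.0, crop_frac = 0.1,
                           p_elastic = 0.2, elastic_sd = 2.0,
                           p_aniso = 0.2, aniso_range = c(1.5, 3.0)) {
  structure(as.list(environment()), class = "cbct_augment_params")
}

# gaussian blur by explicit shift-and-sum along each axis (edge clamp)
.gauss_blur <- function(arr, sd) {
  if (sd <= 0) return(arr)
  r <- max(1L, ceiling(2.5 * sd))
  w <- exp(-(seq(-r, r))^2 / (2 * sd^2)); w <- w / sum(w)
  d <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (t in seq(-r, r)) {
      idx <- clamp(seq_len(n) + t, 1L, n)
      shifted <- switch(axis,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[t + r + 1L] * shifted
    }
    arr <- out
  }
  arr
}

# 0-based voxel-centre index grids of an array
.index_grid <- function(d) {
  list(x = rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
       y = rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
       z = rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# sample image (linear) and target (nearest / linear-per-channel) at
# continuous 0-based source coordinates
.apply_geom <- function(image, target, cx, cy, cz) {
  d <- dim(image)[1:3]
  res_img <- function(a) array(sample_trilinear(a, cx, cy, cz), d)
  res_lab <- function(a) array(sample_nearest(a, cx, cy, cz), d)
  image <- if (length(dim(image)) == 4L) {
    array(apply(image, 4L, function(a) sample_trilinear(array(a, d), cx, cy, cz)),
          dim(image))
  } else res_img(image)
  if (length(dim(target)) == 4L) { # soft target: linear per channel + renorm
    C <- dim(target)[4]
    probs <- vapply(seq_len(C),
                    function(c) sample_trilinear(target[, , , c], cx, cy, cz),
                    numeric(prod(d)))
    probs <- pmax(probs, 0)
    probs <- probs / rowSums(probs)
    target <- array(probs, c(d, C))
  } else {
    target <- res_lab(target)
    storage.mode(target) <- "integer"
  }
  list(image = image, target = target)
}

# rotation (about `axis`, degrees) composed with uniform scaling about the
# array centre; returns 0-based source coordinates for each output voxel
.rot_scale_coords <- function(d, axis = 3L, theta_deg = 0, scale = 1) {
  g <- .index_grid(d)
  ctr <- (d - 1) / 2
  u <- g$x - ctr[1]; v <- g$y - ctr[2]; w <- g$z - ctr[3]
  th <- -theta_deg * pi / 180 # inverse mapping
  cs <- cos(th); sn <- sin(th)
  if (axis == 3L) { a <- cs * u - sn * v; b <- sn * u + cs * v; u <- a; v <- b }
  else if (axis == 1L) { a <- cs * v - sn * w; b <- sn * v + cs * w; v <- a; w <- b }
  else { a <- cs * u + sn * w; b <- -sn * u + cs * w; u <- a; w <- b }
  list(x = u / scale + ctr[1], y = v / scale + ctr[2], z = w / scale + ctr[3])
}

# smooth random displacement field from a coarse control grid (voxels)
.elastic_coords <- function(d, sd, grid = 4L) {
  g <- .index_grid(d)
  disp <- function() {
    ctrl <- array(rnorm(grid^3, sd = sd), c(grid, grid, grid))
    full <- resample_array(ctrl, rep(1, 3), (grid - 1) / pmax(d - 1, 1), "linear")
    as.vector(full[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])])
  }
  list(x = g$x + disp(), y = g$y + disp(), z = g$z + disp())
}

#' Apply training augmentations to an image/target pair
#'
#' Uses the current RNG state; seed outside (e.g. [with_seed()]) for
#' reproducibility. With all probabilities zero this is the identity.
#'
#' @param image 3D array, or 4D `(x, y, z, C)` channels-last array.
#' @param target integer label array (3D) or soft-target array (4D).
#' @param stage `"coarse"` or `"fine"`; the fine stage skips elastic
#'   deformation and anisotropy.
#' @param params an [augment_params()].
#' @return list with augmented `image` and `target`.
#' @export
augment <- function(image, target, stage = c("coarse", "fine"),
                    params = augment_params()) {
  stage <- match.arg(stage)
  stopifnot(inherits(params, "cbct_augment_params"))
  d <- dim(image)[1:3]

  # geometric: rotation and/or scaling share one resampling pass
  theta <- 0; axis <- 3L; sc <- 1
  if (runif(1) < params$p_rotate) {
    axis <- sample(1:3, 1L)
    theta <- runif(1, -params$rotate_deg_max, params$rotate_deg_max)
  }
  if (runif(1) < params$p_scale)
    sc <- runif(1, params$scale_range[1], params$scale_range[2])
  if (theta != 0 || sc != 1) {
    co <- .rot_scale_coords(d, axis, theta, sc)
    r <- .apply_geom(image, target, co$x, co$y, co$z)
    image <- r$image; target <- r$target
  }
  if (stage == "coarse" && runif(1) < params$p_elastic) {
    co <- .elastic_coords(d, params$elastic_sd)
    r <- .apply_geom(image, target, co$x, co$y, co$z)
    image <- r$image; target <- r$target
  }
  if (runif(1) < params$p_crop) {
    keep <- pmax(2L, round(d * (1 - runif(3, 0, params$crop_frac))))
    org <- vapply(1:3, function(a) sample.int(d[a] - keep[a] + 1L, 1L), integer(1))
    g <- .index_grid(d)
    # crop then resample back to the original grid (zoom into the crop)
    cx <- org[1] - 1 + g$x * (keep[1] - 1) / max(d[1] - 1, 1)
    cy <- org[2] - 1 + g$y * (keep[2] - 1) / max(d[2] - 1, 1)
    cz <- org[3] - 1 + g$z * (keep[3] - 1) / max(d[3] - 1, 1)
    r <- .apply_geom(image, target, cx, cy, cz)
    image <- r$image; target <- r$target
  }
  # intensity-only transforms (image unchanged in geometry, target untouched)
  blur3 <- function(a) .gauss_blur(a, runif(1, 0.25, params$blur_sd_max))
  if (runif(1) < params$p_blur) {
    image <- if (length(dim(image)) == 4L) {
      image[, , , 1] <- blur3(image[, , , 1, drop = TRUE]); image
    } else blur3(image)
  }
  if (runif(1) < params$p_noise) {
    ns <- rnorm(prod(d), sd = params$noise_sd)
    if (length(dim(image)) == 4L) image[, , , 1] <- image[, , , 1] + ns
    else image <- image + array(ns, d)
  }
  if (stage == "coarse" && runif(1) < params$p_aniso) {
    f <- runif(1, params$aniso_range[1], params$aniso_range[2])
    axis <- sample(1:3, 1L)
    sp_dn <- rep(1, 3); sp_dn[axis] <- f
    dn_up <- function(a) {
      dn <- resample_array(a, rep(1, 3), sp_dn, "linear")
      up <- resample_array(dn, sp_dn, rep(1, 3), "linear")
      up[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
    }
    image <- if (length(dim(image)) == 4L) {
      image[, , , 1] <- dn_up(image[, , , 1, drop = TRUE]); image
    } else dn_up(image)
  }
  list(image = image, target = target)
}
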