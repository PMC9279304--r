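test_that("dataset splits have rounded-fraction sizes and are reproducible", {
  ids <- sprintf("s%02d", 1:20)
  sp <- split_dataset(ids, c(0.9, 0.05, 0.05), seed = 7)
  expect_equal(lengths(sp), c(train = 18L, dev = 1L, test = 1L))
  expect_identical(sp, split_dataset(ids, c(0.9, 0.05, 0.05), seed = 7))
  expect_error(split_dataset(ids[1:2]), "at least 3")
})

test_that("splits are always disjoint and exhaustive", {
  for (r in 1:50) {
    n <- withr::with_seed(r, sample(3:40, 1))
    ids <- paste0("x", seq_len(n))
    sp <- split_dataset(ids, seed = r)
    all_ids <- c(sp$train, sp$dev, sp$test)
    expect_equal(sort(all_ids), sort(ids))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("combined loss: perfect prediction, uniform closed form, random oracle", {
  # one-hot prediction equal to the hard target
  lab <- withr::with_seed(1, sample(0:2, 27, TRUE))
  sc <- matrix(-50, 27, 3)
  sc[cbind(1:27, lab + 1)] <- 50
  l <- combined_loss(sc, lab)
  expect_lt(l$loss, 1e-6)
  expect_lt(l$ce, 1e-6)

  # uniform 2-class prediction: CE = ln 2
  l2 <- combined_loss(matrix(0, 10, 2), rep(0L, 10))
  expect_equal(l2$ce, log(2), tolerance = 1e-9)

  # random 4^3 patch, 3 classes vs direct-summation oracle
  sc3 <- withr::with_seed(2, matrix(rnorm(64 * 3), 64, 3))
  g3 <- withr::with_seed(3, matrix(runif(64 * 3), 64, 3))
  g3 <- g3 / rowSums(g3)
  expect_equal(combined_loss(sc3, g3)$loss, oracle_combined_loss(sc3, g3),
               tolerance = 1e-6)
})

test_that("loss is nonnegative with Jaccard in [0, 1]; hard targets equal their one-hot", {
  for (s in 1:10) {
    sc <- withr::with_seed(s, matrix(rnorm(125 * 4, sd = 3), 125, 4))
    lab <- withr::with_seed(s + 50, sample(0:3, 125, TRUE))
    l <- combined_loss(sc, lab)
    expect_gte(l$loss, 0)
    expect_gte(l$jaccard, 0); expect_lte(l$jaccard, 1)
    oh <- matrix(0, 125, 4); oh[cbind(1:125, lab + 1)] <- 1
    expect_equal(l$loss, combined_loss(sc, oh)$loss, tolerance = 1e-12)
  }
  expect_error(combined_loss(matrix(NaN, 2, 2), c(0L, 1L)), "non-finite")
  expect_error(combined_loss(matrix(0, 2, 2), c(0L, 5L)), "out of range")
})

test_that("loss gradient matches finite differences", {
  sc <- withr::with_seed(9, matrix(rnorm(27 * 3), 27, 3))
  g <- withr::with_seed(10, matrix(runif(27 * 3), 27, 3)); g <- g / rowSums(g)
  an <- combined_loss(sc, g, grad = TRUE)$dscores
  h <- 1e-6
  for (i in c(1, 14, 40, 81)) {
    sp <- sc; sp[i] <- sp[i] + h; lp <- combined_loss(sp, g)$loss
    sp[i] <- sc[i] - h; lm <- combined_loss(sp, g)$loss
    expect_equal(an[i], (lp - lm) / (2 * h), tolerance = 1e-5)
  }
})

test_that("one-cycle schedule hits its endpoints and is unimodal", {
  total <- 400L
  w <- round(0.05 * total)
  expect_equal(one_cycle_lr(w, total), 1e-3)
  expect_equal(one_cycle_lr(total - 1L, total), 1e-6)
  lrs <- one_cycle_lr(0:(total - 1L), total)
  peak <- which.max(lrs)
  expect_true(all(diff(lrs[1:peak]) >= -1e-15))
  expect_true(all(diff(lrs[peak:total]) <= 1e-15))
  expect_error(one_cycle_lr(0, 1), "total_steps")
})

test_that("augmentation with zero probabilities is the identity and is seed-reproducible", {
  img <- withr::with_seed(1, array(runif(10^3), c(10, 10, 10)))
  lab <- withr::with_seed(2, array(sample(0:5, 10^3, TRUE), c(10, 10, 10)))
  p0 <- augment_params(p_blur = 0, p_noise = 0, p_rotate = 0, p_scale = 0,
                       p_crop = 0, p_elastic = 0, p_aniso = 0)
  a0 <- withr::with_seed(3, augment(img, lab, "coarse", p0))
  expect_identical(a0$image, img)
  expect_identical(a0$target, lab)

  pfull <- augment_params(p_blur = 1, p_noise = 1, p_rotate = 1, p_scale = 1,
                          p_elastic = 1, p_aniso = 1)
  a1 <- withr::with_seed(11, augment(img, lab, "coarse", pfull))
  a2 <- withr::with_seed(11, augment(img, lab, "coarse", pfull))
  expect_identical(a1, a2)
  expect_false(identical(a1$image, img))
})

test_that("a 90-degree rotation matches the hand-rotated oracle", {
  d <- c(9, 9, 5)
  img <- withr::with_seed(4, array(runif(prod(d)), d))
  lab <- array(0L, d)
  lab[2:4, 2, ] <- 5L; lab[2, 2:6, ] <- 3L # L-shaped structure
  co <- cbctseg:::.rot_scale_coords(d, axis = 3L, theta_deg = 90, scale = 1)
  r <- cbctseg:::.apply_geom(img, lab, co$x, co$y, co$z)
  # oracle: +90 deg about z maps output (i,j) from input (j, n-1-i)
  want_lab <- array(0L, d)
  for (i in 1:9) for (j in 1:9)
    want_lab[i, j, ] <- lab[j, 9 + 1 - i, ]
  expect_identical(r$target, want_lab)
  want_img <- array(0, d)
  for (i in 1:9) for (j in 1:9) want_img[i, j, ] <- img[j, 9 + 1 - i, ]
  expect_equal(r$image, want_img, tolerance = 1e-9)
})

test_that("patch queue: per-volume counts, bounded occupancy, faithful patches", {
  cfg <- train_config(patch_size = 4L, samples_per_volume = 20L,
                      queue_capacity = 180L)
  dims <- list(c(10, 10, 10), c(8, 12, 9), c(16, 6, 7))
  q <- patch_queue(dims, cfg, seed = 5)
  expect_length(q$patches, 60L)
  vols <- vapply(q$patches, `[[`, integer(1), "vol")
  expect_equal(as.vector(table(vols)), rep(20L, 3))
  expect_lte(q$max_occupancy, 180L)

  # small queue forces interleaved emission and still respects the bound
  cfg2 <- train_config(patch_size = 4L, samples_per_volume = 8L,
                       queue_capacity = 10L)
  q2 <- patch_queue(dims, cfg2, seed = 6)
  expect_length(q2$patches, 24L)
  expect_lte(q2$max_occupancy, 10L)

  # emitted patch voxels equal the source voxels at the recorded origin
  arr <- withr::with_seed(7, array(rnorm(10 * 10 * 10), c(10, 10, 10)))
  for (pd in q$patches[vols == 1][1:5]) {
    p <- extract_patch(arr, pd$origin, 4L)
    o <- pd$origin
    expect_identical(p, arr[o[1]:(o[1] + 3), o[2]:(o[2] + 3), o[3]:(o[3] + 3)])
  }
  expect_error(patch_queue(list(c(3, 3, 3)), cfg, 1), "smaller than patch")
})

test_that("training reduces loss, selects the best-dev checkpoint, and is reproducible", {
  ph <- generate_phantom_cohort(4, phantom_config(shape = c(16, 16, 16),
                                                  r_end = 3, r_waist = 2),
                                seed = 9)
  pcfg <- pipeline_config(coarse_spacing = 2, fine_spacing = 1,
                          base_channels = 4, depth = 2, patch_size = 8,
                          overlap = 4, k_folds = 2)
  samples <- lapply(names(ph), function(id)
    cbctseg:::prepare_coarse_sample(id, ph[[id]]$volume, ph[[id]]$labels, pcfg))
  ds <- list(train = samples[1:3], dev = samples[4])
  cfg <- train_config(epochs = 5, seed = 21, patch_size = 8)
  run <- function() train_stage(ds, cfg,
                                build_model(model_config("coarse", 6, 4, 2), 2))
  ck <- run()
  expect_lt(tail(ck$log$train_loss, 1), ck$log$train_loss[1])
  expect_equal(ck$best_epoch, which.min(ck$log$dev_loss))
  expect_equal(ck$best_dev_loss, min(ck$log$dev_loss))
  ck2 <- run()
  expect_identical(ck$log, ck2$log)
})

test_that("a tiny model learns a linearly separable voxelwise toy problem", {
  dims <- c(4, 4, 4)
  m <- build_model(model_config("coarse", 2, base_channels = 4, depth = 2), 5)
  x <- withr::with_seed(6, matrix(rnorm(prod(dims)), ncol = 1))
  tgt <- as.integer(x > 0) # class = sign of the input voxel
  opt <- cbctseg:::adam_init(m$params)
  loss <- NA
  for (step in 0:199) {
    fw <- unet_forward(m, x, dims, train = TRUE)
    ls <- combined_loss(fw$scores, tgt, grad = TRUE)
    gr <- unet_backward(m, ls$dscores, fw$cache)
    upd <- cbctseg:::adam_step(m$params, gr, opt, 1e-2)
    m$params <- upd$params; opt <- upd$state
    loss <- ls$loss
  }
  expect_lt(loss, 0.1)
})
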