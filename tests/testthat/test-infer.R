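test_that("tiling: single tile, the stride-128 case, and exhaustive coverage", {
  p1 <- plan_tiles(c(32, 32, 32), 32, 16)
  expect_equal(nrow(p1$origins), 1L)
  expect_equal(unname(p1$origins[1, ]), c(1L, 1L, 1L))

  # 272-long axis, patch 144, overlap 16: stride 128, origins {0, 128} 0-based
  p2 <- plan_tiles(c(272, 144, 144), 144, 16)
  expect_equal(sort(unique(p2$origins[, 1])) - 1L, c(0L, 128L))
  expect_equal(max(p2$origins[, 1]) + 144L - 1L, 272L)

  for (r in 1:50) {
    sh <- withr::with_seed(r, sample(5:60, 3, TRUE))
    ps <- withr::with_seed(r + 100, sample(4:20, 1))
    ov <- withr::with_seed(r + 200, sample(1:(ps - 1), 1))
    plan <- plan_tiles(sh, ps, ov)
    covered <- array(0L, plan$padded_shape)
    for (t in seq_len(nrow(plan$origins))) {
      o <- plan$origins[t, ]
      covered[o[1]:(o[1] + ps - 1), o[2]:(o[2] + ps - 1), o[3]:(o[3] + ps - 1)] <-
        covered[o[1]:(o[1] + ps - 1), o[2]:(o[2] + ps - 1), o[3]:(o[3] + ps - 1)] + 1L
    }
    expect_true(all(covered >= 1L))
    for (ax in 1:3) {
      org <- sort(unique(plan$origins[, ax]))
      if (length(org) > 1) expect_true(all(diff(org) <= ps - ov))
    }
  }
  expect_error(plan_tiles(c(10, 10, 10), 8, 8), "overlap")
})

test_that("weight map is centre-heavy, symmetric, and floored", {
  w <- make_weight_map(c(12, 10, 8))
  expect_true(all(w > 0))
  ctr <- w[6, 5, 4]
  expect_equal(max(w), ctr)
  expect_gte(min(w), 0.01 * max(w) - 1e-12)
  expect_lt(w[1, 1, 1], ctr)
  expect_equal(w, w[12:1, , ]); expect_equal(w, w[, 10:1, ])
  expect_equal(w, w[, , 8:1])
})

test_that("aggregation: identity, constants, and a per-voxel brute-force oracle", {
  # single tile covering the volume
  plan <- plan_tiles(c(8, 8, 8), 8, 4)
  pr <- withr::with_seed(1, array(runif(8^3 * 3), c(8, 8, 8, 3)))
  pr <- pr / as.vector(array(rowSums(matrix(pr, ncol = 3)), c(8, 8, 8)))
  out <- aggregate_patches(list(pr), plan)
  expect_equal(out$probs, pr, tolerance = 1e-12)

  # constant predictions aggregate to the same constant
  plan2 <- plan_tiles(c(12, 8, 8), 8, 4)
  cst <- array(rep(c(0.5, 0.3, 0.2), each = 8^3), c(8, 8, 8, 3))
  out2 <- aggregate_patches(rep(list(cst), nrow(plan2$origins)), plan2)
  expect_equal(max(abs(out2$probs[, , , 1] - 0.5)), 0, tolerance = 1e-12)

  # random multi-tile case vs direct per-voxel weighted average
  for (r in 1:10) {
    sh <- withr::with_seed(300 + r, sample(6:14, 3, TRUE))
    plan3 <- plan_tiles(sh, 6, 2)
    w <- make_weight_map(6)
    preds <- withr::with_seed(400 + r, lapply(seq_len(nrow(plan3$origins)),
      function(i) array(runif(6^3 * 2), c(6, 6, 6, 2))))
    got <- aggregate_patches(preds, plan3, w)
    # oracle: loop tiles, accumulate
    num <- array(0, c(plan3$padded_shape, 2)); den <- array(0, plan3$padded_shape)
    for (t in seq_len(nrow(plan3$origins))) {
      o <- plan3$origins[t, ]
      for (c in 1:2) {
        num[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5), c] <-
          num[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5), c] + w * preds[[t]][,,,c]
      }
      den[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5)] <-
        den[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5)] + w
    }
    want <- (num / as.vector(den))[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3]), ,
                                   drop = FALSE]
    expect_equal(got$probs, want, tolerance = 1e-6)
  }
  expect_error(aggregate_patches(list(pr, pr), plan), "planned tiles")
})

test_that("uniform weights reduce aggregation to a plain average", {
  plan <- plan_tiles(c(10, 6, 6), 6, 3)
  preds <- withr::with_seed(5, lapply(seq_len(nrow(plan$origins)),
    function(i) array(runif(6^3 * 2), c(6, 6, 6, 2))))
  wu <- array(1, c(6, 6, 6))
  got <- aggregate_patches(preds, plan, wu)
  num <- array(0, c(plan$padded_shape, 2)); cnt <- array(0, plan$padded_shape)
  for (t in seq_len(nrow(plan$origins))) {
    o <- plan$origins[t, ]
    for (c in 1:2)
      num[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5), c] <-
        num[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5), c] + preds[[t]][,,,c]
    cnt[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5)] <-
      cnt[o[1]:(o[1]+5), o[2]:(o[2]+5), o[3]:(o[3]+5)] + 1
  }
  want <- (num / as.vector(cnt))[1:10, 1:6, 1:6, , drop = FALSE]
  expect_equal(got$probs, want, tolerance = 1e-12)
})

test_that("tiling and re-aggregating a probability field is lossless", {
  gt <- tiny_labels(c(14, 10, 9), seed = 8)
  probs <- cbctseg:::one_hot(gt$labels, 6)
  plan <- plan_tiles(dim(gt$labels), 6, 2)
  padded <- cbctseg:::pad_to(probs, plan$padded_shape, 0, background_channel = 1)
  tiles <- lapply(seq_len(nrow(plan$origins)), function(t)
    extract_patch(padded, plan$origins[t, ], 6L))
  out <- aggregate_patches(tiles, plan)
  expect_equal(out$probs, probs, tolerance = 1e-12)
})

test_that("argmax ties break toward the lowest class index", {
  m <- matrix(c(0.4, 0.4, 0.2,
                0.3, 0.3, 0.4,
                0.5, 0.1, 0.5), 3, 3, byrow = TRUE)
  expect_equal(cbctseg:::argmax_rows(m), c(1L, 3L, 1L))
})

test_that("the two-stage pipeline produces valid, deterministic label maps", {
  ph <- generate_head_phantom(phantom_config(shape = c(16, 16, 16),
                                             r_end = 3, r_waist = 2, seed = 31))
  coarse <- build_model(model_config("coarse", 6, 2, 2), 1)
  fine <- build_model(model_config("fine", 6, 2, 2), 2)
  as_ckpt <- function(m) structure(list(model = m, best_epoch = 1L,
                                        best_dev_loss = 0, log = data.frame(),
                                        config = train_config(), train_ids = "x"),
                                   class = "cbct_checkpoint")
  out1 <- predict_volume(ph$volume, as_ckpt(coarse), as_ckpt(fine),
                         coarse_spacing = 2, fine_spacing = 1,
                         patch_size = 8, overlap = 4)
  out2 <- predict_volume(ph$volume, as_ckpt(coarse), as_ckpt(fine),
                         coarse_spacing = 2, fine_spacing = 1,
                         patch_size = 8, overlap = 4)
  expect_true(all(out1$labels %in% 0:5))
  expect_identical(out1$labels, out2$labels)
  expect_equal(dim(out1$labels), c(16L, 16L, 16L))
})
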