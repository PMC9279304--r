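test_that("ICC(3,1): perfect agreement, hand-table oracle, shift invariance", {
  x <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(icc_two_way_mixed(measurement_table(x)), 1.0)

  hand <- cbind(c(9, 6, 8, 7, 10), c(9.5, 6.5, 9, 8, 10.5))
  t5 <- measurement_table(hand)
  expect_equal(icc_two_way_mixed(t5), oracle_icc31(hand), tolerance = 1e-10)

  # consistency ICC is unchanged by per-method constant offsets
  shifted <- sweep(hand, 2, c(100, -40), "+")
  expect_equal(icc_two_way_mixed(measurement_table(shifted)),
               icc_two_way_mixed(t5), tolerance = 1e-12)
  # and by a global additive constant
  expect_equal(icc_two_way_mixed(measurement_table(hand + 3)),
               icc_two_way_mixed(t5), tolerance = 1e-12)
  expect_error(icc_two_way_mixed(measurement_table(matrix(2, 3, 2))),
               "zero total variance")
})

test_that("ICC recovers the variance-components ratio in simulation", {
  t <- generate_measurement_table(n = 500, methods = 2, between_subject_sd = 3,
                                  noise_sd = 1, seed = 42)
  expect_equal(icc_two_way_mixed(t), 0.9, tolerance = 0.03 / 0.9)
})

test_that("reliability classification uses the 0.75 / 0.90 thresholds", {
  expect_equal(classify_reliability(0.92), "excellent")
  expect_equal(classify_reliability(0.954), "excellent")
  expect_equal(classify_reliability(0.80), "good")
  expect_equal(classify_reliability(0.76), "good")
  expect_equal(classify_reliability(0.50), "below_good")
  expect_equal(classify_reliability(0.75), "below_good")
  expect_equal(classify_reliability(0.90), "good")
})

test_that("Mann-Whitney U: separation, symmetry, exhaustive oracle", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  x <- c(2, 4, 9, 4)
  expect_equal(mann_whitney_u(x, x)$U, length(x)^2 / 2)

  for (r in 1:25) {
    n1 <- withr::with_seed(r, sample(2:6, 1))
    n2 <- withr::with_seed(r + 100, sample(2:6, 1))
    a <- withr::with_seed(r + 200, sample(1:8, n1, TRUE)) # ties likely
    b <- withr::with_seed(r + 300, sample(1:8, n2, TRUE))
    got <- mann_whitney_u(a, b)
    want <- oracle_mwu(a, b)
    expect_equal(got$U, want$U, label = sprintf("draw %d U", r))
    expect_equal(got$p, want$p, tolerance = 1e-12,
                 label = sprintf("draw %d p", r))
    expect_equal(got$method, "exact")
  }
})

test_that("large-sample MWU agrees with wilcox.test without continuity correction", {
  x <- withr::with_seed(1, rnorm(30))
  y <- withr::with_seed(2, rnorm(25, 0.5))
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, min(ref$statistic, 30 * 25 - ref$statistic),
               ignore_attr = TRUE)
  expect_error(mann_whitney_u(numeric(0), y), "empty")
})

test_that("Kruskal-Wallis: identical groups, rank-formula oracle, kruskal.test", {
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2), c(2, 1)))$H, 0,
               tolerance = 1e-12)

  g <- list(c(6.4, 6.8, 7.2), c(8.5, 9.4, 7.7, 8.1), c(1.3, 2.0, 2.7, 2.8))
  got <- kruskal_wallis(g)
  expect_equal(got$H, oracle_kw_h(g), tolerance = 1e-10)
  ref <- stats::kruskal.test(unlist(g), factor(rep(1:3, lengths(g))))
  expect_equal(got$H, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  # with ties
  gt <- list(c(1, 2, 2, 3), c(2, 3, 3, 4), c(4, 4, 5, 5))
  reft <- stats::kruskal.test(unlist(gt), factor(rep(1:3, lengths(gt))))
  expect_equal(kruskal_wallis(gt)$H, unname(reft$statistic), tolerance = 1e-10)
})

test_that("for two groups the KW chi-square p equals the MWU normal p (H = z^2)", {
  for (r in 1:10) {
    x <- withr::with_seed(r, rnorm(12))
    y <- withr::with_seed(r + 50, rnorm(15, 0.3))
    pk <- kruskal_wallis(list(x, y))$p
    pm <- mann_whitney_u(x, y, exact_max = 0)$p
    expect_equal(pk, pm, tolerance = 1e-6)
  }
})

test_that("compare_methods flags shifts and reports clean tables faithfully", {
  # zero noise, no bias: perfect agreement
  t0 <- generate_measurement_table(20, methods = c("manual", "automatic"),
                                   noise_sd = 0, per_method_bias = 0, seed = 1)
  r0 <- compare_methods(list(volume_cc = t0))
  expect_equal(r0$volume_cc$icc_overall, 1.0)
  expect_equal(r0$volume_cc$reliability_overall, "excellent")
  expect_false(any(r0$volume_cc$pairwise$significant))

  # a large location shift in one method must be flagged
  ts <- generate_measurement_table(30, methods = 2, per_method_bias = c(0, 50),
                                   noise_sd = 0.5, between_subject_sd = 1,
                                   seed = 2)
  rs <- compare_methods(list(volume_cc = ts))
  expect_true(all(rs$volume_cc$pairwise$significant))

  # summary statistics match direct recomputation; 3 methods trigger KW
  t3 <- generate_measurement_table(15, methods = 3, seed = 3)
  r3 <- compare_methods(list(area_mm2 = t3))
  expect_equal(r3$area_mm2$summary$mean, unname(colMeans(t3$values)))
  expect_equal(r3$area_mm2$summary$sd, unname(apply(t3$values, 2, sd)))
  expect_false(is.null(r3$area_mm2$kruskal_wallis))
  expect_equal(nrow(r3$area_mm2$pairwise), 3L)
})

test_that("long-format measurement CSV round-trips into tables", {
  t <- generate_measurement_table(6, methods = c("manual", "dc"), seed = 5)
  df <- data.frame(subject = rep(rownames(t$values), 2),
                   method = rep(colnames(t$values), each = 6),
                   metric = "volume_cc",
                   value = as.vector(t$values))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_measurements(path)
  expect_equal(back$volume_cc$values[, colnames(t$values)], t$values,
               ignore_attr = TRUE)
})
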