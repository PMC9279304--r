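# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (plain loops, direct formulas) rather than
# calling package internals.

# brute-force trilinear interpolation of `arr` at one 0-based coordinate,
# with edge clamping
oracle_trilinear <- function(arr, x, y, z) {
  d <- dim(arr)
  x <- min(max(x, 0), d[1] - 1); y <- min(max(y, 0), d[2] - 1)
  z <- min(max(z, 0), d[3] - 1)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  s <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fx else fx
    wy <- if (dy == 0) 1 - fy else fy
    wz <- if (dz == 0) 1 - fz else fz
    s <- s + wx * wy * wz *
      arr[min(x0 + dx, d[1] - 1) + 1, min(y0 + dy, d[2] - 1) + 1,
          min(z0 + dz, d[3] - 1) + 1]
  }
  s
}

# full brute-force linear resample (loops over every output voxel)
oracle_resample_linear <- function(arr, spacing, target) {
  d <- dim(arr)
  nd <- pmax(1L, as.integer(ceiling(d * spacing / target)))
  out <- array(0, nd)
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    out[i, j, k] <- oracle_trilinear(arr,
                                     (i - 1) * target[1] / spacing[1],
                                     (j - 1) * target[2] / spacing[2],
                                     (k - 1) * target[3] / spacing[3])
  }
  out
}

# direct-summation combined loss (no shared code with the implementation)
oracle_combined_loss <- function(scores, g, eps = 1e-6) {
  p <- t(apply(scores, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  ce <- -mean(sapply(seq_len(nrow(p)), function(v) sum(g[v, ] * log(p[v, ]))))
  jc <- sapply(seq_len(ncol(p)), function(c) {
    inter <- sum(p[, c] * g[, c])
    (inter + eps) / (sum(p[, c]) + sum(g[, c]) - inter + eps)
  })
  ce + (1 - mean(jc))
}

# exhaustive Mann-Whitney oracle: U from all pairwise comparisons, exact
# two-sided p by enumerating every assignment of the pooled values
oracle_mwu <- function(x, y) {
  u_stat <- function(a, b) {
    ua <- 0
    for (xi in a) for (yj in b)
      ua <- ua + (xi > yj) + 0.5 * (xi == yj)
    min(ua, length(a) * length(b) - ua)
  }
  u <- u_stat(x, y)
  pool <- c(x, y)
  n1 <- length(x)
  sets <- utils::combn(length(pool), n1)
  us <- apply(sets, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  list(U = u, p = mean(us <= u + 1e-9))
}

# direct rank-formula Kruskal-Wallis H with tie correction
oracle_kw_h <- function(groups) {
  v <- unlist(groups); N <- length(v)
  r <- rank(v)
  gidx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(sapply(seq_along(groups), function(j) sum(r[gidx == j])^2 / sum(gidx == j))) -
    3 * (N + 1)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# ANOVA sum-of-squares ICC(3,1) oracle via stats::aov
oracle_icc31 <- function(values) {
  df <- data.frame(y = as.vector(values),
                   subj = factor(rep(seq_len(nrow(values)), ncol(values))),
                   meth = factor(rep(seq_len(ncol(values)), each = nrow(values))))
  ms <- summary(stats::aov(y ~ subj + meth, data = df))[[1]][, "Mean Sq"]
  k <- ncol(values)
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3])
}
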