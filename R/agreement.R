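#' Subjects-by-methods measurement table
#'
#' Container for one airway metric measured on the same subjects by several
#' methods (e.g. manual, automatic, third-party software).
#'
#' @param values n x k numeric matrix, no missing cells, n >= 2 subjects in
#'   rows, k >= 2 methods in columns.
#' @param subjects,methods optional row/column ids.
#' @return a `cbct_measurement_table`.
#' @export
measurement_table <- function(values, subjects = NULL, methods = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stopf("measurement table has missing cells")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stopf("need >= 2 subjects and >= 2 methods")
  rownames(values) <- subjects %||% rownames(values) %||% paste0("s", seq_len(nrow(values)))
  colnames(values) <- methods %||% colnames(values) %||% paste0("m", seq_len(ncol(values)))
  structure(list(values = values), class = "cbct_measurement_table")
}

#' Read a long-format measurement CSV
#'
#' Expects columns `subject`, `method`, `value` (and optionally `metric`; one
#' table is returned per metric).
#'
#' @param path CSV path.
#' @return a `cbct_measurement_table`, or a named list of them when a `metric`
#'   column is present.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "method", "value")
  if (!all(need %in% names(df))) stopf("CSV must have columns %s", paste(need, collapse = ", "))
  make <- function(dd) {
    wide <- tapply(dd$value, list(dd$subject, dd$method), mean)
    measurement_table(wide)
  }
  if ("metric" %in% names(df)) lapply(split(df, df$metric), make) else make(df)
}

# two-way (subjects x methods) ANOVA mean squares
.twoway_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm_ - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation, two-way mixed model
#'
#' Default is ICC(3,1): single-rater consistency from the two-way mixed-effects
#' ANOVA, `(MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error)`.
#' Average-measure consistency ICC(3,k) and single-rater absolute agreement
#' ICC(2,1) are available for sensitivity analyses.
#'
#' @param t a [measurement_table()].
#' @param type `"ICC3_1"` (default), `"ICC3_k"` or `"ICC2_1"`.
#' @return the ICC estimate (in `[-1, 1]`).
#' @export
icc_two_way_mixed <- function(t, type = c("ICC3_1", "ICC3_k", "ICC2_1")) {
  stopifnot(inherits(t, "cbct_measurement_table"))
  type <- match.arg(type)
  ms <- .twoway_ms(t$values)
  if (ms$msr == 0 && ms$mse == 0) stopf("zero total variance")
  switch(type,
    ICC3_1 = (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse),
    ICC3_k = (ms$msr - ms$mse) / ms$msr,
    ICC2_1 = (ms$msr - ms$mse) /
      (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n))
}

#' Classify an ICC against the standard reliability thresholds
#' @param icc finite ICC value.
#' @return `"excellent"` (> 0.90), `"good"` (> 0.75) or `"below_good"`.
#' @export
classify_reliability <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc > 0.90) "excellent" else if (icc > 0.75) "good" else "below_good"
}

# midranks + tie counts of a combined sample
.midranks <- function(v) {
  r <- rank(v, ties.method = "average")
  tie <- table(v)
  list(r = r, ties = as.numeric(tie[tie > 1]))
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U_x, U_y)` computed from midranks. The two-sided p-value
#' is exact (full enumeration of group assignments, valid under ties) when
#' both samples have at most `exact_max` observations, otherwise it uses the
#' normal approximation with tie-corrected variance and no continuity
#' correction (so that for two groups the Kruskal-Wallis H equals z^2).
#'
#' @param x,y numeric samples (nonempty).
#' @param exact_max maximum per-group size for exact enumeration (default 8).
#' @return list: `U`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) < 1L || length(y) < 1L) stopf("empty sample")
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  r <- rank(comb, ties.method = "average")
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  u <- min(ux, uy)
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- utils::combn(n1 + n2, n1)
    rs <- colSums(matrix(r[sets], nrow = n1))
    ustar <- pmin(rs - n1 * (n1 + 1) / 2, n1 * n2 - (rs - n1 * (n1 + 1) / 2))
    p <- mean(ustar <= u + 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie <- table(comb); tt <- as.numeric(tie[tie > 1])
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sig2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (ux - n1 * n2 / 2) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(U = u, p = min(p, 1), method = method)
}

#' Kruskal-Wallis H test
#'
#' H computed from midranks with the tie correction, referred to a chi-square
#' distribution with g - 1 degrees of freedom.
#'
#' @param groups list of >= 2 nonempty numeric samples.
#' @return list: `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v, ties.method = "average")
  rs <- tapply(r, g, sum)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(v); tt <- as.numeric(tie[tie > 1])
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr == 0) return(list(H = 0, p = 1, df = length(groups) - 1L))
  h <- h / corr
  df <- length(groups) - 1L
  list(H = h, p = pchisq(h, df, lower.tail = FALSE), df = df)
}

#' Compare measurement methods for one or more metrics
#'
#' For each metric table: per-method summary statistics; a Mann-Whitney U test
#' for two methods or a Kruskal-Wallis H test (plus pairwise MWU) for three or
#' more; ICC for every method pair and over all methods; significance flags at
#' `alpha`, and reliability classes at the 0.75/0.90 thresholds.
#'
#' @param tables a named list of [measurement_table()]s (or a single table).
#' @param alpha significance level (default 0.05).
#' @param icc_type ICC variant, see [icc_two_way_mixed()].
#' @return a `cbct_agreement_report` list, one element per metric.
#' @export
compare_methods <- function(tables, alpha = 0.05, icc_type = "ICC3_1") {
  if (inherits(tables, "cbct_measurement_table")) tables <- list(metric = tables)
  out <- lapply(names(tables), function(metric) {
    t <- tables[[metric]]
    x <- t$values
    k <- ncol(x)
    summ <- data.frame(method = colnames(x),
                       mean = colMeans(x),
                       median = apply(x, 2L, median),
                       min = apply(x, 2L, min), max = apply(x, 2L, max),
                       sd = apply(x, 2L, sd), row.names = NULL)
    pairs <- utils::combn(k, 2L)
    pw <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      mwu <- mann_whitney_u(x[, a], x[, b])
      sub <- measurement_table(x[, c(a, b), drop = FALSE])
      icc <- icc_two_way_mixed(sub, icc_type)
      data.frame(method_a = colnames(x)[a], method_b = colnames(x)[b],
                 U = mwu$U, p = mwu$p, significant = mwu$p < alpha,
                 icc = icc, reliability = classify_reliability(icc))
    })
    pw <- do.call(rbind, pw)
    kw <- if (k >= 3L) kruskal_wallis(asplit(x, 2L)) else NULL
    icc_all <- icc_two_way_mixed(t, icc_type)
    list(metric = metric, summary = summ, pairwise = pw, kruskal_wallis = kw,
         icc_overall = icc_all,
         reliability_overall = classify_reliability(icc_all),
         alpha = alpha, icc_type = icc_type)
  })
  names(out) <- names(tables)
  structure(out, class = "cbct_agreement_report")
}

#' @export
print.cbct_agreement_report <- function(x, ...) {
  for (m in names(x)) {
    r <- x[[m]]
    cat(sprintf("== %s ==\n", m))
    print(r$summary, row.names = FALSE, digits = 4)
    if (!is.null(r$kruskal_wallis))
      cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
                  r$kruskal_wallis$H, r$kruskal_wallis$df, r$kruskal_wallis$p))
    print(r$pairwise, row.names = FALSE, digits = 4)
    cat(sprintf("Overall %s = %.4f (%s)\n", r$icc_type, r$icc_overall,
                r$reliability_overall))
  }
  invisible(x)
}
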