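#' @useDynLib cbctseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median sd pnorm pchisq setNames
#' @importFrom utils head tail write.csv read.csv
NULL

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never clobber the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# row-major-agnostic helper: argmax over columns of a V x C matrix with
# ties broken by the lowest class index (column order)
argmax_rows <- function(m) {
  max.col(m, ties.method = "first")
}
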