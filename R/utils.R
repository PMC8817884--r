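#' @useDynLib eegdepth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft var sd median quantile rnorm runif approx
#' @importFrom utils read.table write.table head tail
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded package internals never clobber user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_numeric_vector <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) == 0L)
    stopf("`%s` must be a nonempty numeric vector", name)
  if (anyNA(x)) stopf("`%s` contains NA/NaN values", name)
  invisible(x)
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic mixing keeps per-subject streams independent while the whole
#' cohort stays a pure function of one master seed. Result is kept within the
#' 32-bit integer range.
#'
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
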