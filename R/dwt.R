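# Discrete wavelet transform (Mallat pyramid) with periodic extension.
# Orthonormal Daubechies filters; db4 is the package default basis.

daubechies_filters <- function(wavelet) {
  lo <- switch(tolower(wavelet),
    "haar" = , "db1" = c(1, 1) / sqrt(2),
    "db2" = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    "db4" = c(0.23037781330885523, 0.71484657055254153,
              0.63088076792959036, -0.02798376941698385,
              -0.18703481171888114, 0.03084138183598697,
              0.03288301166698295, -0.01059740178499728),
    stopf("unknown wavelet '%s'; supported: haar/db1, db2, db4", wavelet)
  )
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1L)   # quadrature mirror filter
  list(lo = lo, hi = hi, len = n)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
  Fl <- filt$len
  # circular correlation then dyadic downsampling: a_k = sum_j h_j x[(2k-2+j-1) mod n + 1]
  idx <- outer(2L * seq_len(n %/% 2L) - 2L, seq_len(Fl) - 1L, "+") %% n + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L)
  list(approx = drop(xm %*% filt$lo), detail = drop(xm %*% filt$hi))
}

#' Multilevel discrete wavelet transform
#'
#' Pyramid decomposition with periodic boundary handling (odd-length levels
#' are extended by repeating the final sample). Returns the detail
#' coefficients per level plus the final approximation.
#'
#' @param x numeric vector, `length(x) >= 2^levels`.
#' @param wavelet basis name: `"haar"`/`"db1"`, `"db2"` or `"db4"` (default).
#' @param levels decomposition depth (>= 1).
#' @return list with `details` (list of length `levels`, coarse scales last)
#'   and `approx` (final approximation coefficients).
#' @export
dwt <- function(x, wavelet = "db4", levels = 5L) {
  assert_numeric_vector(x)
  levels <- as.integer(levels)
  if (levels < 1L) stopf("`levels` must be >= 1")
  max_lev <- floor(log2(length(x)))
  if (length(x) < 2^levels)
    stopf("signal of length %d supports at most %d levels (requested %d)",
          length(x), max_lev, levels)
  filt <- daubechies_filters(wavelet)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, filt)
    details[[j]] <- st$detail
    a <- st$approx
  }
  list(details = details, approx = a)
}
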