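# Independent brute-force oracles used to validate the package numerics.
# These share no code with the implementation: direct loops and textbook
# sums only.

# O(N^2) template-counting sample entropy (Chebyshev, self-matches excluded)
oracle_sampen <- function(x, m, r) {
  N <- length(x)
  n <- N - m
  A <- 0; B <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# approximate entropy with self-matches included
oracle_apen <- function(x, m, r) {
  phi <- function(m) {
    N <- length(x)
    n <- N - m + 1
    lc <- numeric(n)
    for (i in 1:n) {
      cnt <- 0
      for (j in 1:n)
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) cnt <- cnt + 1
      lc[i] <- log(cnt / n)
    }
    mean(lc)
  }
  phi(m) - phi(m + 1)
}

# ordinal-pattern histogram permutation entropy (order() tie convention)
oracle_pe <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  pats <- vapply(seq_len(n), function(i)
    paste(order(x[i + (0:(m - 1)) * tau]), collapse = "."), "")
  p <- as.vector(table(pats)) / n
  -sum(p * log(p)) / log(factorial(m))
}

# wavelet entropy recomputed term by term from the decomposition
oracle_we <- function(x, wavelet, levels) {
  dec <- dwt(x, wavelet, levels)
  E <- c(vapply(dec$details, function(d) sum(d^2), 0), sum(dec$approx^2))
  P <- E / sum(E)
  P <- P[P > 0]
  -sum(P * log(P))
}

# one-sided periodogram band power via an explicit DFT double sum
oracle_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  xc <- x - mean(x)
  k <- seq_len(floor(n / 2))
  om <- outer(2 * pi * k / n, 0:(n - 1))
  re <- cos(om) %*% xc
  im <- -sin(om) %*% xc
  p <- (re^2 + im^2) / n^2
  dbl <- rep(2, length(k))
  if (n %% 2 == 0) dbl[length(k)] <- 1
  f <- k * fs / n
  sum((p * dbl)[f >= f_lo & f < f_hi])
}

oracle_band_ratio <- function(x, fs, num, den) {
  log10(oracle_band_power(x, fs, num[1], num[2]) /
          oracle_band_power(x, fs, den[1], den[2]))
}

# Pearson correlation via hand-expanded sums
oracle_cor <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# small seeded sample set for training bookkeeping tests: depth is a linear
# function of a few pixels plus noise, several pseudo-subjects
tiny_sample_set <- function(n = 60, seed = 7, n_subjects = 5) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 576), n, 576)
    y <- pmin(100, pmax(0, 55 + 25 * x[, 1] + 10 * x[, 300] + rnorm(n, 0, 2)))
    structure(list(x = x, y = y,
                   subject_id = rep_len(sprintf("T%02d", seq_len(n_subjects)), n),
                   time = seq_len(n), phase = rep("maintenance", n)),
              class = "SampleSet")
  })
}
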