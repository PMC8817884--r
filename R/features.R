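# Per-epoch EEG sedation indices: sample entropy, permutation entropy,
# wavelet entropy, band ratios, spectral summaries, and documented surrogate
# indices, assembled into a fixed 48-indicator feature schema.

#' Default entropy parameters
#'
#' Embedding length 2 and tolerance 0.2 x epoch SD over 500-sample windows
#' for sample entropy; order 4, lag 1 for permutation entropy; db4 basis at
#' 5 levels for wavelet entropy.
#'
#' @return named list of parameters.
#' @export
entropy_params <- function(sampen_m = 2L, sampen_r = 0.2, sampen_N = 500L,
                           pe_m = 4L, pe_tau = 1L,
                           we_wavelet = "db4", we_levels = 5L) {
  if (sampen_m < 1L) stopf("sampen_m must be >= 1")
  if (sampen_r <= 0) stopf("sampen_r must be > 0")
  if (pe_m < 2L) stopf("pe_m must be >= 2")
  if (pe_tau < 1L) stopf("pe_tau must be >= 1")
  if (we_levels < 1L) stopf("we_levels must be >= 1")
  list(sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
       sampen_N = as.integer(sampen_N), pe_m = as.integer(pe_m),
       pe_tau = as.integer(pe_tau), we_wavelet = we_wavelet,
       we_levels = as.integer(we_levels))
}

#' Sample entropy
#'
#' Negative natural log of the conditional probability that template pairs
#' matching within Chebyshev tolerance `r` at length `m` also match at
#' `m + 1`. Self-matches are excluded (Richman-Moorman convention). `r` is in
#' the units of `x`; callers using the common 0.2-of-SD convention convert
#' before calling (as [extract_features()] does).
#'
#' @param x numeric vector of length `N > m + 1`.
#' @param m template length (>= 1).
#' @param r absolute tolerance (> 0).
#' @return nonnegative value, or `NA_real_` when no template pair matches at
#'   either length (undefined).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  assert_numeric_vector(x)
  m <- as.integer(m)
  if (length(x) <= m + 1L)
    stopf("sample entropy needs N > m + 1 (N = %d, m = %d)", length(x), m)
  if (!is.finite(r) || r <= 0) stopf("tolerance r must be > 0")
  cnt <- sampen_counts_cpp(as.numeric(x), m, r)
  if (cnt[1L] == 0 || cnt[2L] == 0) return(NA_real_)
  -log(cnt[2L] / cnt[1L])
}

#' Approximate entropy
#'
#' Pincus' ApEn: `Phi^m(r) - Phi^{m+1}(r)` with self-matches included,
#' Chebyshev distance. Provided as a documented stand-in index (the usual
#' companion of sample entropy in depth-of-anesthesia work).
#'
#' @inheritParams sample_entropy
#' @return nonnegative value.
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  assert_numeric_vector(x)
  m <- as.integer(m)
  if (length(x) <= m + 1L)
    stopf("approximate entropy needs N > m + 1 (N = %d, m = %d)", length(x), m)
  if (!is.finite(r) || r <= 0) stopf("tolerance r must be > 0")
  x <- as.numeric(x)
  apen_phi_cpp(x, m, r) - apen_phi_cpp(x, m + 1L, r)
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of lagged length-`m`
#' windows, normalized by `log(m!)` so the value lies in \[0, 1\]: 0 for a
#' single pattern (e.g. a monotone series), 1 when all `m!` patterns are
#' equally frequent. Ties are broken by position (first occurrence ranks
#' lower).
#'
#' @param x numeric vector with `length(x) >= (m - 1) * tau + 2`.
#' @param m pattern order, `2 <= m <= 8`.
#' @param tau lag (>= 1).
#' @return value in \[0, 1\].
#' @export
permutation_entropy <- function(x, m = 4L, tau = 1L) {
  assert_numeric_vector(x)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L || m > 8L) stopf("pattern order m must be in 2..8")
  if (tau < 1L) stopf("lag tau must be >= 1")
  n_win <- length(x) - (m - 1L) * tau
  if (n_win < 2L)
    stopf("series too short: need length >= (m-1)*tau + 2 = %d",
          (m - 1L) * tau + 2L)
  # ordinal pattern code from all pairwise comparisons (vectorized over
  # windows); ties resolve to "earlier element ranks lower"
  base <- seq_len(n_win)
  code <- integer(n_win)
  bit <- 1L
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      xa <- x[base + (a - 1L) * tau]
      xb <- x[base + (b - 1L) * tau]
      code <- code + bit * (xa > xb)
      bit <- bit * 2L
    }
  }
  p <- tabulate(match(code, unique(code)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(factorial(m))
}

#' Wavelet entropy
#'
#' Shannon entropy of the relative wavelet energies across scales: the
#' per-scale energies are the summed squared detail coefficients of a
#' `levels`-deep decomposition plus the final approximation, normalized to
#' probabilities. Natural log, so the value lies in \[0, log(levels + 1)\].
#'
#' @param x numeric vector, `length(x) >= 2^levels`.
#' @param wavelet basis name (see [dwt()]).
#' @param levels decomposition depth.
#' @param return_energies also return the relative energies.
#' @return entropy value, or a list with `entropy` and `rel_energy` when
#'   `return_energies = TRUE`.
#' @export
wavelet_entropy <- function(x, wavelet = "db4", levels = 5L,
                            return_energies = FALSE) {
  dec <- dwt(x, wavelet = wavelet, levels = levels)
  E <- c(vapply(dec$details, function(d) sum(d^2), 0), sum(dec$approx^2))
  tot <- sum(E)
  if (tot <= 0) {
    S <- 0
    P <- rep(NA_real_, length(E))
  } else {
    P <- E / tot
    nz <- P > 0
    S <- -sum(P[nz] * log(P[nz]))
  }
  if (return_energies) list(entropy = S, rel_energy = P) else S
}

#' Surrogate indices: ApEn, SFS and SpEn stand-ins
#'
#' Three sedation indices that appear by name in the monitoring literature
#' without a published formula; this package provides documented stand-ins:
#' ApEn is standard approximate entropy ([approximate_entropy()]); SFS
#' ("synch fast slow") is `log10` of broadband 0.5-47 Hz power over fast
#' 40-47 Hz power; SpEn is the Shannon entropy of the normalized PSD on
#' (0, 47\] Hz. All three are flagged `surrogate = TRUE` in the feature
#' schema.
#'
#' @param x numeric epoch.
#' @param fs sampling rate (Hz).
#' @param m,r approximate-entropy parameters (r absolute).
#' @return named numeric `c(apen, sfs, spen)`.
#' @export
surrogate_indices <- function(x, fs, m = 2L, r = 0.2 * stats::sd(x)) {
  apen <- if (stats::sd(x) > 0) approximate_entropy(x, m, r) else 0
  p_all <- band_power(x, fs, 0.5, min(47, fs / 2 - 1e-9))
  p_fast <- band_power(x, fs, 40, min(47, fs / 2 - 1e-9))
  sfs <- if (p_fast > 0 && p_all > 0) log10(p_all / p_fast) else NA_real_
  est <- psd_estimate(x, fs)
  sel <- est$freq > 0 & est$freq <= 47
  p <- est$psd[sel]
  spen <- if (sum(p) > 0) {
    q <- p / sum(p); qnz <- q[q > 0]
    -sum(qnz * log(qnz))
  } else NA_real_
  c(apen = apen, sfs = sfs, spen = spen)
}

# -- feature schema -----------------------------------------------------------

sub_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       sigma = c(12, 15), beta1 = c(15, 21), beta2 = c(21, 30),
       gamma = c(30, 47))
}

#' The 48-indicator feature schema
#'
#' Fixed, ordered schema of the per-epoch indicator vector: 11 full-band
#' indices (sample/permutation/wavelet entropy, the three band ratios, SFS,
#' MPF, SEF95, ApEn, SpEn), 7 classical sub-bands x 4 indices each
#' (log power, relative power, permutation entropy and sample entropy of the
#' band-limited signal), 5 time-domain descriptors (Hjorth activity, mobility
#' and complexity, zero-crossing rate, line length) and the 4 covariates
#' (height, weight, age, sex) — 48 values per epoch in total.
#'
#' @return data frame with columns `name`, `kind` (`"eeg"`/`"covariate"`) and
#'   `surrogate` (TRUE for the stand-in indices).
#' @export
feature_schema <- function() {
  base <- c("sampen", "peen", "we", "alpha_ratio", "beta_ratio", "bma_ratio",
            "sfs", "mpf", "sef95", "apen", "spen")
  bands <- names(sub_bands())
  per_band <- as.vector(t(outer(c("logpow", "relpow", "peen", "sampen"),
                                bands, paste, sep = "_")))
  timed <- c("hjorth_activity", "hjorth_mobility", "hjorth_complexity",
             "zcr", "line_length")
  cov <- c("height", "weight", "age", "sex")
  nm <- c(base, per_band, timed, cov)
  data.frame(
    name = nm,
    kind = c(rep("eeg", length(nm) - 4L), rep("covariate", 4L)),
    surrogate = nm %in% c("sfs", "apen", "spen"),
    stringsAsFactors = FALSE
  )
}

# band-limit an epoch by FFT masking (zero-phase, periodic)
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                     # fold to physical frequency
  X[!(f >= f_lo & f < f_hi)] <- 0+0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

hjorth_params <- function(x) {
  dx <- diff(x); ddx <- diff(dx)
  a <- stats::var(x)
  mob <- if (a > 0) sqrt(stats::var(dx) / a) else NA_real_
  cmp <- if (stats::var(dx) > 0) sqrt(stats::var(ddx) / stats::var(dx)) / mob
         else NA_real_
  c(hjorth_activity = a, hjorth_mobility = mob, hjorth_complexity = cmp)
}

epoch_features <- function(x, fs, params, bands_spec) {
  sdx <- stats::sd(x)
  r_abs <- params$sampen_r * sdx
  se <- if (sdx > 0) sample_entropy(x, params$sampen_m, r_abs) else 0
  pe <- permutation_entropy(x, params$pe_m, params$pe_tau)
  we <- wavelet_entropy(x, params$we_wavelet, params$we_levels)
  est <- psd_estimate(x, fs)
  df <- est$freq[2L] - est$freq[1L]
  bp <- function(b) {
    sel <- est$freq >= b[1L] & est$freq < b[2L]
    sum(est$psd[sel]) * df
  }
  lr <- function(num, den) {
    en <- bp(num); ed <- bp(den)
    if (en > 0 && ed > 0) log10(en / ed) else NA_real_
  }
  ss <- spectral_summaries_from_psd(est$freq, est$psd)
  sur <- surrogate_indices(x, fs, params$sampen_m,
                           if (sdx > 0) r_abs else 1)
  out <- c(sampen = se, peen = pe, we = we,
           alpha_ratio = lr(bands_spec$alpha_num, bands_spec$alpha_den),
           beta_ratio = lr(bands_spec$beta_num, bands_spec$beta_den),
           bma_ratio = lr(bands_spec$bma_num, bands_spec$bma_den),
           sfs = unname(sur["sfs"]), mpf = unname(ss["mpf"]),
           sef95 = unname(ss["sef95"]), apen = unname(sur["apen"]),
           spen = unname(sur["spen"]))
  sb <- sub_bands()
  tot <- bp(c(0.5, min(47, fs / 2 - 1e-9)))
  for (b in names(sb)) {
    lim <- c(sb[[b]][1L], min(sb[[b]][2L], fs / 2 - 1e-9))
    pw <- bp(lim)
    xb <- fft_bandpass(x, fs, lim[1L], lim[2L])
    sdb <- stats::sd(xb)
    v <- c(if (pw > 0) log10(pw) else NA_real_,
           if (tot > 0) pw / tot else NA_real_,
           permutation_entropy(xb, params$pe_m, params$pe_tau),
           if (sdb > 0) sample_entropy(xb, params$sampen_m,
                                       params$sampen_r * sdb) else 0)
    names(v) <- paste(c("logpow", "relpow", "peen", "sampen"), b, sep = "_")
    out <- c(out, v)
  }
  zcr <- mean(diff(sign(x - mean(x))) != 0)
  ll <- mean(abs(diff(x)))
  c(out, hjorth_params(x), zcr = zcr, line_length = ll)
}

#' Extract the per-epoch feature table
#'
#' Computes the full 48-indicator schema ([feature_schema()]) for every epoch
#' of an `EpochedSignal` and appends the subject covariates. Undefined index
#' values (degenerate epochs, empty bands) are imputed with the subject
#' median of that indicator (0 when every epoch is undefined), so the table
#' is NA-free as the downstream sample builder requires.
#'
#' @param es an [epoch_signal()] result.
#' @param profile named list/vector with `height`, `weight`, `age`, `sex`
#'   (sex coded 0/1).
#' @param params [entropy_params()].
#' @param bands [spectral_bands()].
#' @return data frame: `subject_id`, `epoch_time`, then the 48 schema columns.
#' @export
extract_features <- function(es, profile, params = entropy_params(),
                             bands = spectral_bands()) {
  stopifnot(inherits(es, "EpochedSignal"))
  need <- c("height", "weight", "age", "sex")
  if (!all(need %in% names(profile)))
    stopf("profile must provide %s", paste(need, collapse = ", "))
  rows <- lapply(es$epochs, epoch_features, fs = es$fs, params = params,
                 bands_spec = bands)
  m <- do.call(rbind, rows)
  # imputation rule: subject median per indicator, 0 if fully undefined
  for (j in seq_len(ncol(m))) {
    bad <- !is.finite(m[, j])
    if (any(bad)) {
      med <- stats::median(m[!bad, j])
      m[bad, j] <- if (is.finite(med)) med else 0
    }
  }
  sc <- feature_schema()
  eeg_names <- sc$name[sc$kind == "eeg"]
  colnames(m) <- eeg_names
  out <- data.frame(subject_id = es$subject_id, epoch_time = es$epoch_times,
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  out$height <- as.numeric(profile[["height"]])
  out$weight <- as.numeric(profile[["weight"]])
  out$age <- as.numeric(profile[["age"]])
  out$sex <- as.numeric(profile[["sex"]])
  out
}

#' Write / read a feature table
#'
#' Tab-delimited, one row per epoch, header in schema order after the
#' `subject_id` and `epoch_time` columns.
#'
#' @param tab feature table from [extract_features()].
#' @param path file path.
#' @return `path` invisibly; [read_features()] returns the table.
#' @export
write_features <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
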