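# Power spectral density estimation (periodogram and Welch) plus band-power
# integration, the log band ratios, spectral summaries and the STFT
# spectrogram.

#' Power spectral density estimate
#'
#' One-sided PSD of a demeaned signal. `method = "periodogram"` is the plain
#' squared DFT; `method = "welch"` (the default used by the feature
#' extractor) averages modified periodograms of Hann-windowed segments of
#' length `min(length(x), nseg)` with 50 % overlap. Scaling is such that the
#' integral of the density over (0, fs/2) equals the biased signal variance
#' (up to the estimator's leakage).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param method `"welch"` or `"periodogram"`.
#' @param nseg Welch segment length cap (default 256).
#' @return list with `freq` (Hz) and `psd` (power per Hz), DC bin removed.
#' @export
psd_estimate <- function(x, fs, method = c("welch", "periodogram"),
                         nseg = 256L) {
  assert_numeric_vector(x)
  method <- match.arg(method)
  if (method == "periodogram") {
    n <- length(x)
    X <- stats::fft(x - mean(x))
    df <- fs / n
    k <- seq_len(floor(n / 2))                 # bins 1 .. n/2 (excl. DC)
    p <- (Mod(X[k + 1L])^2) / n^2 / df
    dbl <- rep(2, length(k))
    if (n %% 2L == 0L) dbl[length(k)] <- 1     # Nyquist bin not mirrored
    list(freq = k * df, psd = p * dbl)
  } else {
    n <- length(x)
    L <- min(n, as.integer(nseg))
    step <- max(1L, L %/% 2L)
    starts <- seq(1L, n - L + 1L, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)   # Hann
    U <- sum(w^2)
    df <- fs / L
    k <- seq_len(floor(L / 2))
    acc <- numeric(length(k))
    for (s in starts) {
      seg <- x[s:(s + L - 1L)]
      seg <- (seg - mean(seg)) * w
      X <- stats::fft(seg)
      acc <- acc + Mod(X[k + 1L])^2
    }
    p <- acc / length(starts) / (U * fs)
    dbl <- rep(2, length(k))
    if (L %% 2L == 0L) dbl[length(k)] <- 1
    list(freq = k * df, psd = p * dbl)
  }
}

#' Spectral power in a frequency band
#'
#' Integrates the PSD over the half-open band `[f_lo, f_hi)`, so band powers
#' are exactly additive over a partition of the spectrum.
#'
#' @inheritParams psd_estimate
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return nonnegative power (signal units squared).
#' @export
band_power <- function(x, fs, f_lo, f_hi, method = c("welch", "periodogram"),
                       nseg = 256L) {
  method <- match.arg(method)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= fs / 2))
    stopf("band must satisfy 0 <= f_lo < f_hi <= fs/2 (= %g Hz)", fs / 2)
  est <- psd_estimate(x, fs, method = method, nseg = nseg)
  sel <- est$freq >= f_lo & est$freq < f_hi
  if (!any(sel))
    stopf("band [%g, %g) Hz contains no frequency bin at resolution %g Hz",
          f_lo, f_hi, est$freq[2L] - est$freq[1L])
  df <- est$freq[2L] - est$freq[1L]
  sum(est$psd[sel]) * df
}

#' Spectral band definitions for the sedation band ratios
#'
#' The alpha ratio divides 30-42.5 Hz power by 6-12 Hz power; the beta ratio
#' divides 30-42.5 Hz by 12-21 Hz. The (beta-alpha) ratio divides 6-12 Hz by
#' 11-21 Hz as printed in its source (`bma_den_variant = "printed"`); the
#' internally consistent 12-21 Hz denominator is selectable
#' (`bma_den_variant = "beta"`).
#'
#' @param bma_den_variant `"printed"` (11-21 Hz) or `"beta"` (12-21 Hz).
#' @return named list of `c(f_lo, f_hi)` pairs.
#' @export
spectral_bands <- function(bma_den_variant = c("printed", "beta")) {
  bma_den_variant <- match.arg(bma_den_variant)
  list(
    alpha_num = c(30, 42.5), alpha_den = c(6, 12),
    beta_num  = c(30, 42.5), beta_den  = c(12, 21),
    bma_num   = c(6, 12),
    bma_den   = if (bma_den_variant == "printed") c(11, 21) else c(12, 21)
  )
}

#' Logarithmic band-power ratio
#'
#' `log10` of the power in `num_band` over the power in `den_band`. A zero
#' denominator yields `NA` (undefined), not an error.
#'
#' @inheritParams band_power
#' @param num_band,den_band numeric `c(f_lo, f_hi)` band edges (Hz).
#' @return real, or `NA_real_` when the denominator power is zero.
#' @export
band_ratio <- function(x, fs, num_band, den_band,
                       method = c("welch", "periodogram"), nseg = 256L) {
  method <- match.arg(method)
  en <- band_power(x, fs, num_band[1L], num_band[2L], method, nseg)
  ed <- band_power(x, fs, den_band[1L], den_band[2L], method, nseg)
  if (ed <= 0) return(NA_real_)
  if (en <= 0) return(NA_real_)
  log10(en / ed)
}

#' Median power frequency and 95 % spectral edge frequency from a PSD
#'
#' Quantiles of the cumulative power distribution, linearly interpolated on
#' the frequency grid, restricted to `(0, f_max]`.
#'
#' @param freq frequency grid (Hz), increasing.
#' @param psd nonnegative power density on `freq`.
#' @param f_max upper analysis limit in Hz (default 47).
#' @return named numeric `c(mpf, sef95)`; `NA` if total power is zero.
#' @export
spectral_summaries_from_psd <- function(freq, psd, f_max = 47) {
  sel <- freq > 0 & freq <= f_max
  f <- freq[sel]; p <- psd[sel]
  if (!length(f) || sum(p) <= 0) return(c(mpf = NA_real_, sef95 = NA_real_))
  # trapezoidal cumulative power; the density is extended flat from the
  # lowest positive grid point down to 0 Hz so the support is (0, f_max]
  cum <- p[1L] * f[1L] +
    c(0, cumsum((p[-1L] + p[-length(p)]) / 2 * diff(f)))
  tot <- cum[length(cum)]
  if (tot <= 0) {
    # all power in a single bin: both quantiles sit on the peak
    pk <- f[which.max(p)]
    return(c(mpf = pk, sef95 = pk))
  }
  q <- function(alpha) stats::approx(c(0, cum), c(0, f), xout = alpha * tot,
                                     ties = "ordered")$y
  c(mpf = q(0.5), sef95 = q(0.95))
}

#' Median power frequency and spectral edge frequency of a signal
#'
#' @inheritParams psd_estimate
#' @param f_max upper analysis limit (Hz).
#' @return named numeric `c(mpf, sef95)`; `NA` for an all-zero epoch.
#' @export
spectral_summaries <- function(x, fs, f_max = 47,
                               method = c("welch", "periodogram"),
                               nseg = 256L) {
  method <- match.arg(method)
  if (all(x == 0)) return(c(mpf = NA_real_, sef95 = NA_real_))
  est <- psd_estimate(x, fs, method = method, nseg = nseg)
  spectral_summaries_from_psd(est$freq, est$psd, f_max = f_max)
}

#' Short-time Fourier spectrogram
#'
#' Squared one-sided STFT magnitudes. Columns are analysis frames (count
#' `floor((L - win_len)/hop) + 1`), rows are frequencies `0 .. fs/2`. With a
#' rectangular window and non-overlapping frames, `sum(S)/win_len` equals the
#' framed signal energy exactly (Parseval); tapered windows scale energy by
#' the mean squared window.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param win_len window length in samples.
#' @param hop hop size in samples, `1 <= hop <= win_len`.
#' @param window `"hann"` or `"rect"`.
#' @return matrix (freq x time) with attributes `freq` (Hz), `time` (s,
#'   frame centers) and `window`.
#' @export
stft_spectrogram <- function(x, fs, win_len, hop = win_len %/% 2L,
                             window = c("hann", "rect")) {
  assert_numeric_vector(x)
  window <- match.arg(window)
  L <- length(x)
  win_len <- as.integer(win_len); hop <- as.integer(hop)
  if (win_len > L) stopf("win_len = %d exceeds signal length %d", win_len, L)
  if (hop < 1L || hop > win_len) stopf("hop must satisfy 1 <= hop <= win_len")
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / win_len) else rep(1, win_len)
  starts <- seq(0L, L - win_len, by = hop)
  nf <- floor(win_len / 2) + 1L
  S <- matrix(0, nf, length(starts))
  for (i in seq_along(starts)) {
    X <- stats::fft(x[(starts[i] + 1L):(starts[i] + win_len)] * w)
    m2 <- Mod(X[seq_len(nf)])^2
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (win_len %% 2L == 0L) dbl[nf] <- 1
    S[, i] <- m2 * dbl
  }
  attr(S, "freq") <- (seq_len(nf) - 1L) * fs / win_len
  attr(S, "time") <- (starts + win_len / 2) / fs
  attr(S, "window") <- window
  S
}
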