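test_that("sample entropy matches the brute-force template oracle", {
  for (s in 1:12) {
    x <- withr::with_seed(s, rnorm(50 + 10 * s))
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, r), oracle_sampen(x, 2, r),
                 tolerance = 1e-12)
    expect_equal(sample_entropy(x, 3, r), oracle_sampen(x, 3, r),
                 tolerance = 1e-12)
  }
  # alternating series, small tolerance
  alt <- rep(c(1, 2), 15)
  expect_equal(sample_entropy(alt, 2, 0.1), oracle_sampen(alt, 2, 0.1),
               tolerance = 1e-12)
})

test_that("sample entropy closed forms and errors", {
  expect_equal(sample_entropy(rep(3.7, 50), 2, 0.5), 0)
  expect_error(sample_entropy(rnorm(3), 2, 0.1), "N > m")
  expect_error(sample_entropy(rnorm(50), 2, -1), "r must be")
  # no matches at m+1 -> undefined flag
  expect_true(is.na(sample_entropy(c(1, 10, 2, 20, 3, 30, 4, 40), 2, 0.5)))
})

test_that("approximate entropy matches its direct-formula oracle", {
  for (s in 1:6) {
    x <- withr::with_seed(100 + s, rnorm(60))
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, 2, r), oracle_apen(x, 2, r),
                 tolerance = 1e-12)
  }
})

test_that("permutation entropy matches the pattern-histogram oracle", {
  for (s in 1:12) {
    x <- withr::with_seed(200 + s, runif(150))
    expect_equal(permutation_entropy(x, 4, 1), oracle_pe(x, 4, 1),
                 tolerance = 1e-12)
    expect_equal(permutation_entropy(x, 3, 2), oracle_pe(x, 3, 2),
                 tolerance = 1e-12)
  }
  x500 <- withr::with_seed(99, runif(500))
  expect_equal(permutation_entropy(x500, 4, 1), oracle_pe(x500, 4, 1),
               tolerance = 1e-12)
})

test_that("permutation entropy closed forms", {
  expect_equal(permutation_entropy(1:30, 4, 1), 0)
  expect_equal(permutation_entropy(seq(100, 1, length.out = 40), 4, 1), 0)
  # alternating series realizes both order-2 patterns equally often
  expect_equal(permutation_entropy(rep(c(1, 2), 16)[1:31], 2, 1), 1)
  expect_error(permutation_entropy(rnorm(3), 4, 1), "too short")
  expect_error(permutation_entropy(rnorm(50), 1, 1), "order m")
})

test_that("wavelet entropy: relative energies, bounds, oracle agreement", {
  for (s in 1:10) {
    x <- withr::with_seed(300 + s, rnorm(512))
    we <- wavelet_entropy(x, "db4", 5, return_energies = TRUE)
    expect_equal(sum(we$rel_energy), 1, tolerance = 1e-12)
    expect_gte(we$entropy, 0)
    expect_lte(we$entropy, log(6) + 1e-12)
    expect_equal(we$entropy, oracle_we(x, "db4", 5), tolerance = 1e-12)
  }
  # all energy at a single scale: constant signal puts everything in the
  # final approximation
  expect_lte(wavelet_entropy(rep(5, 64), "haar", 3), 1e-6)
  expect_error(wavelet_entropy(rnorm(16), "db4", 5), "at most")
  expect_error(wavelet_entropy(rnorm(64), "sym9", 3), "supported")
})

test_that("entropies are shift-invariant; sample entropy is scale-covariant", {
  x <- withr::with_seed(41, rnorm(120))
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x + 100, 2, r), sample_entropy(x, 2, r))
  expect_equal(permutation_entropy(x + 100, 4, 1),
               permutation_entropy(x, 4, 1))
  expect_equal(sample_entropy(3 * x, 2, 3 * r), sample_entropy(x, 2, r))
})

test_that("band power: tones, additivity, variance normalization", {
  fs <- 125
  t <- (0:1999) / fs
  tone <- sin(2 * pi * 10 * t)
  expect_equal(band_power(rep(0, 500) + 0, fs, 6, 12), 0)
  p_in <- band_power(tone, fs, 6, 12, "periodogram")
  p_out <- band_power(tone, fs, 30, 42.5, "periodogram")
  expect_gt(p_in / max(p_out, 1e-30), 100)
  expect_equal(p_in, 0.5, tolerance = 1e-6)          # ½A² for a unit tone
  x <- withr::with_seed(5, rnorm(1000))
  parts <- band_power(x, fs, 0, 20, "periodogram") +
    band_power(x, fs, 20, 40, "periodogram") +
    band_power(x, fs, 40, fs / 2, "periodogram")
  expect_equal(band_power(x, fs, 0, fs / 2, "periodogram"), parts,
               tolerance = 1e-12)
  # total excludes the Nyquist bin, so agreement is to estimator tolerance
  expect_equal(parts, mean((x - mean(x))^2), tolerance = 1e-3)
  expect_error(band_power(x, fs, 10.01, 10.02, "periodogram"),
               "no frequency bin")
})

test_that("band ratios recover closed-form two-tone power ratios", {
  fs <- 125
  t <- (0:1999) / fs
  two <- 2 * sin(2 * pi * 35 * t) + sin(2 * pi * 10 * t)
  ar <- band_ratio(two, fs, c(30, 42.5), c(6, 12), "periodogram")
  expect_equal(ar, log10(4), tolerance = 0.01)
  expect_equal(band_ratio(two, fs, c(6, 12), c(6, 12)), 0)
  # zero denominator power -> undefined flag, not an error
  expect_true(is.na(band_ratio(rep(0, 500) + 0, fs, c(30, 42.5), c(1, 3),
                               "periodogram")))
  bands <- spectral_bands()
  expect_equal(bands$alpha_num, c(30, 42.5))
  expect_equal(bands$alpha_den, c(6, 12))
  expect_equal(bands$beta_den, c(12, 21))
  expect_equal(bands$bma_den, c(11, 21))
  expect_equal(spectral_bands("beta")$bma_den, c(12, 21))
})

test_that("spectral summaries: tones, flat density, monotone SEF95", {
  fs <- 125
  t <- (0:1999) / fs
  ss <- spectral_summaries(sin(2 * pi * 10 * t), fs, method = "periodogram")
  expect_equal(unname(ss["mpf"]), 10, tolerance = fs / 2000 + 1e-9)
  expect_equal(unname(ss["sef95"]), 10, tolerance = fs / 2000 + 1e-9)
  flat <- spectral_summaries_from_psd(seq(0.5, 40, by = 0.5), rep(1, 80))
  expect_equal(unname(flat), c(20, 38))
  expect_lte(ss["mpf"], ss["sef95"])
  # adding high-frequency power never decreases SEF95
  base <- sin(2 * pi * 10 * t)
  s0 <- spectral_summaries(base, fs, method = "periodogram")["sef95"]
  s1 <- spectral_summaries(base + 0.5 * sin(2 * pi * 40 * t), fs,
                           method = "periodogram")["sef95"]
  expect_gte(s1, s0)
  expect_true(all(is.na(spectral_summaries(rep(0, 500), fs))))
})

test_that("spectrogram geometry, stationarity and energy bookkeeping", {
  fs <- 125
  t <- (0:2499) / fs
  tone <- sin(2 * pi * 10 * t)
  S <- stft_spectrogram(tone, fs, 250, 250, window = "rect")
  expect_equal(ncol(S), floor((2500 - 250) / 250) + 1)
  # stationary tone: identical columns
  expect_lt(max(abs(S - S[, 1])), 1e-9 * max(S))
  # Parseval with rectangular non-overlapping frames
  expect_equal(sum(S) / 250, sum(tone^2), tolerance = 1e-9)
  # two concatenated tones: per-segment argmax frequency
  two <- c(sin(2 * pi * 10 * t[1:1250]), sin(2 * pi * 30 * t[1:1250]))
  S2 <- stft_spectrogram(two, fs, 250, 250, window = "hann")
  f <- attr(S2, "freq")
  am <- f[apply(S2, 2, which.max)]
  expect_true(all(abs(am[1:5] - 10) <= fs / 250))
  expect_true(all(abs(am[6:10] - 30) <= fs / 250))
  # halving the window doubles time columns and doubles the bin width
  Sh <- stft_spectrogram(tone, fs, 125, 125)
  expect_equal(ncol(Sh), 2 * ncol(S))
  expect_equal(diff(attr(Sh, "freq"))[1], 2 * diff(attr(S, "freq"))[1])
  expect_error(stft_spectrogram(tone, fs, 5000, 100), "exceeds")
})

test_that("surrogate indices behave and match direct recomputation", {
  fs <- 125
  expect_equal(unname(surrogate_indices(rep(1, 500), fs, r = 0.1)["apen"]), 0)
  t <- (0:499) / fs
  tone <- sin(2 * pi * 10 * t)
  expect_lt(unname(surrogate_indices(tone, fs)["spen"]), 1)
  x <- withr::with_seed(17, rnorm(500))
  sur <- surrogate_indices(x, fs, 2, 0.2 * sd(x))
  expect_equal(unname(sur["apen"]), oracle_apen(x, 2, 0.2 * sd(x)),
               tolerance = 1e-10)
  est <- psd_estimate(x, fs)
  sel <- est$freq > 0 & est$freq <= 47
  q <- est$psd[sel] / sum(est$psd[sel])
  expect_equal(unname(sur["spen"]), -sum(q * log(q)), tolerance = 1e-10)
  p_all <- band_power(x, fs, 0.5, 47)
  p_fast <- band_power(x, fs, 40, 47)
  expect_equal(unname(sur["sfs"]), log10(p_all / p_fast), tolerance = 1e-10)
})

test_that("the feature schema is fixed at 48 ordered indicators", {
  sc <- feature_schema()
  expect_equal(nrow(sc), 48)
  expect_equal(sum(sc$kind == "covariate"), 4)
  expect_equal(sc$name[1:3], c("sampen", "peen", "we"))
  expect_equal(tail(sc$name, 4), c("height", "weight", "age", "sex"))
  expect_true(all(c("sfs", "apen", "spen") %in% sc$name[sc$surrogate]))
  expect_false(any(duplicated(sc$name)))
})

test_that("extract_features produces an NA-free table in schema order", {
  rec <- raw_recording(withr::with_seed(8, rnorm(1500, sd = 20)), 125)
  es <- epoch_signal(bandpass_filter(rec), 500)
  ft <- extract_features(es, list(height = 170, weight = 70, age = 50,
                                  sex = 1))
  expect_equal(nrow(ft), 3)
  expect_equal(names(ft), c("subject_id", "epoch_time", feature_schema()$name))
  expect_false(anyNA(ft))
  expect_equal(unique(ft$height), 170)
  # round trip through the delimited writer
  p <- tempfile(fileext = ".tsv")
  write_features(ft, p)
  back <- read_features(p)
  expect_equal(back[, -1], ft[, -1], tolerance = 1e-12)
  expect_error(extract_features(es, list(height = 1)), "profile")
})
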