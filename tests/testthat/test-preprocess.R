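test_that("band-pass filter preserves in-band tones and rejects out-of-band", {
  fs <- 125
  t <- (0:3749) / fs
  tone10 <- raw_recording(sin(2 * pi * 10 * t), fs)
  out <- bandpass_filter(tone10, 0.5, 47, 4)
  # compare RMS over the interior to avoid edge transients
  mid <- 500:3250
  expect_equal(sqrt(mean(out$samples[mid]^2)),
               sqrt(mean(tone10$samples[mid]^2)), tolerance = 0.01)

  # 60 Hz requires fs > 120; use a tone just below Nyquist instead of mains
  fs2 <- 250
  t2 <- (0:4999) / fs2
  tone60 <- raw_recording(sin(2 * pi * 60 * t2), fs2)
  out60 <- bandpass_filter(tone60, 0.5, 47, 4)
  expect_lt(sqrt(mean(out60$samples^2)), 0.1 * sqrt(mean(tone60$samples^2)))

  zero <- raw_recording(rep(0, 1000) + 0, fs)
  expect_equal(bandpass_filter(zero)$samples, rep(0, 1000))
})

test_that("band-pass filter validates its band and order", {
  rec <- raw_recording(rnorm(1000), 125)
  expect_error(bandpass_filter(rec, 0.5, 80), "fs/2")
  expect_error(bandpass_filter(rec, 30, 10), "fs/2")
  expect_error(bandpass_filter(rec, 0.5, 47, order = 0), "order")
})

test_that("epoching follows the sliding-window count formula", {
  mk <- function(L) raw_recording(seq_len(L) + 0, 125)
  expect_length(epoch_signal(mk(1500), 500, 0)$epochs, 3L)
  expect_length(epoch_signal(mk(1499), 500, 0)$epochs, 2L)
  expect_length(epoch_signal(mk(1000), 500, 250)$epochs, 3L)
  # sliding-window oracle across assorted geometries
  for (case in list(c(2000, 500, 0), c(2000, 500, 100), c(777, 250, 125))) {
    L <- case[1]; N <- case[2]; ov <- case[3]
    es <- epoch_signal(mk(L), N, ov)
    starts <- seq(1, L - N + 1, by = N - ov)
    expect_length(es$epochs, length(starts))
    expect_equal(es$epochs[[length(starts)]],
                 seq(starts[length(starts)], length.out = N))
    expect_true(all(diff(es$epoch_times) > 0))
    expect_true(all(lengths(es$epochs) == N))
  }
  expect_error(epoch_signal(mk(400), 500), "at least N = 500")
  expect_error(epoch_signal(mk(1000), 500, 500), "overlap")
})

test_that("filtering commutes with epoching at identical boundaries", {
  rec <- raw_recording(withr::with_seed(1, rnorm(2000)), 125)
  a <- epoch_signal(bandpass_filter(rec), 500)
  filt <- bandpass_filter(rec)
  b_epochs <- lapply(epoch_signal(rec, 500)$epochs, function(e) e) # raw epochs
  # epoching the filtered signal must equal slicing the filtered vector
  for (i in seq_along(a$epochs))
    expect_equal(a$epochs[[i]], filt$samples[(i - 1) * 500 + 1:500])
})

test_that("epoch tables and delimited recordings round-trip", {
  rec <- raw_recording(withr::with_seed(2, rnorm(1500)), 125, subject_id = "S9")
  es <- epoch_signal(rec, 500)
  path <- tempfile(fileext = ".tsv")
  write_epochs(es, path)
  back <- read_epochs(path)
  for (i in seq_along(es$epochs))
    expect_equal(back$epochs[[i]], es$epochs[[i]], tolerance = 1e-6)
  expect_equal(back$epoch_times, es$epoch_times)
  expect_equal(back$fs, es$fs)
  expect_equal(back$subject_id, "S9")

  txt <- tempfile(fileext = ".txt")
  writeLines(c("time_s\tamplitude_uV",
               paste((0:999) / 125, rec$samples[1:1000], sep = "\t")), txt)
  rec2 <- read_eeg_text(txt)
  expect_equal(rec2$fs, 125, tolerance = 1e-6)
  expect_equal(rec2$samples, rec$samples[1:1000])
})

test_that("EDF files round-trip a recording within quantization error", {
  rec <- raw_recording(withr::with_seed(3, rnorm(1000, sd = 30)), 125,
                       subject_id = "EDF1")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 125)
  expect_length(back$samples, 1000)
  # 16-bit quantization over the data range
  qstep <- diff(range(rec$samples)) / 65535
  expect_lt(max(abs(back$samples - rec$samples)), qstep)
  expect_error(read_edf(path, channel = "EMG"), "no EDF channel")
  expect_equal(read_edf(path, channel = 1)$samples, back$samples)
})

test_that("recordings reject or drop NA samples as configured", {
  x <- c(rnorm(100), NA, rnorm(50))
  expect_error(raw_recording(x, 125), "NA")
  rec <- raw_recording(x, 125, na_action = "drop")
  expect_length(rec$samples, 150)
  expect_error(raw_recording(numeric(0), 125))
  expect_error(raw_recording(rnorm(10), -1), "positive")
})

test_that("depth trajectories enforce range and contiguous phases", {
  tr <- depth_trajectory(0:9, c(105, 90, 80, 60, 40, 35, 35, 50, 70, 95),
                         c(rep("induction", 5), rep("maintenance", 2),
                           rep("recovery", 3)))
  expect_true(all(tr$depth >= 0 & tr$depth <= 100))
  expect_equal(tr$depth[1], 100)                    # clipped
  expect_error(depth_trajectory(0:3, rep(50, 4), c("a", "a", "b", "b")),
               "unknown phase")
  expect_error(depth_trajectory(0:3, rep(50, 4),
                                c("induction", "maintenance", "induction",
                                  "maintenance")),
               "contiguous")
  at <- depth_at(tr, c(0.2, 7.9, 30))
  expect_equal(at$depth[1:2], c(100, 70))
  expect_true(is.na(at$depth[3]))                   # beyond tolerance
})
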