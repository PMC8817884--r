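# Seeded synthetic anesthesia cohorts: single-channel EEG whose spectral
# balance tracks a latent 0-100 depth trajectory through induction,
# maintenance and recovery, plus demographic profiles and a noisy reference
# depth series, so the whole pipeline runs without clinical recordings.

#' Generator settings for a synthetic cohort
#'
#' The latent depth index falls from `depth_awake` to `depth_plateau` during
#' induction, wanders slightly around the plateau during maintenance, and
#' rises to `depth_end` during recovery. EEG is a mixture of a slow
#' (0.5-4 Hz) and a fast (15-40 Hz) band-limited noise process whose power
#' ratio is log-linear in the depth index (`log(P_fast/P_slow) =
#' ratio_c0 + ratio_c1 * depth/100`), a constant mid band (4-15 Hz) and
#' broadband noise; an additional depth-dependent one-pole smoothing makes
#' deep EEG more regular. The reference "monitor" series is the latent depth
#' plus Gaussian observation noise (SD `ref_noise_sd`), clipped to
#' \[0, 100\], sampled at 1 Hz.
#'
#' @param n_subjects cohort size (default 93).
#' @param fs sampling rate, Hz.
#' @param dur_induction,dur_maintenance,dur_recovery phase durations, s.
#' @param depth_awake,depth_plateau,depth_end depth level anchors (0-100).
#' @param ratio_c0,ratio_c1 intercept/slope of the log fast-slow power ratio.
#' @param gain_jitter_sd stationary SD of the slow multiplicative log-gain
#'   jitter applied independently to each spectral band (emulates the
#'   electrode/EMG/vigilance disturbances that keep single clinical indices
#'   in the moderate correlation band; 0 disables).
#' @param gain_jitter_ar per-second AR(1) coefficient of the jitter
#'   (correlation time of a few seconds).
#' @param rms_uV overall signal RMS scale, microvolts.
#' @param ref_noise_sd observation noise SD of the reference series.
#' @param seed master seed; every subject stream derives from it.
#' @return a `GeneratorSpec` list.
#' @export
generator_spec <- function(n_subjects = 93L, fs = 125,
                           dur_induction = 120, dur_maintenance = 240,
                           dur_recovery = 120,
                           depth_awake = 92, depth_plateau = 35,
                           depth_end = 88,
                           ratio_c0 = -3, ratio_c1 = 5,
                           gain_jitter_sd = 0.8, gain_jitter_ar = 0.85,
                           rms_uV = 20, ref_noise_sd = 3, seed = 1L) {
  if (n_subjects < 1L) stopf("n_subjects must be >= 1")
  stopifnot(fs > 0, dur_induction > 0, dur_maintenance > 0, dur_recovery > 0,
            rms_uV > 0, ref_noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects), fs = fs,
                 dur_induction = dur_induction,
                 dur_maintenance = dur_maintenance,
                 dur_recovery = dur_recovery,
                 depth_awake = depth_awake, depth_plateau = depth_plateau,
                 depth_end = depth_end, ratio_c0 = ratio_c0,
                 ratio_c1 = ratio_c1, gain_jitter_sd = gain_jitter_sd,
                 gain_jitter_ar = gain_jitter_ar, rms_uV = rms_uV,
                 ref_noise_sd = ref_noise_sd, seed = as.integer(seed)),
            class = "GeneratorSpec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lo | out > hi))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Sample demographic profiles
#'
#' Heights, weights and ages are truncated normals within the published
#' cohort ranges (height 158-180 cm, weight 54-93 kg, age 22-83 yr); sex is
#' Bernoulli with the cohort's male fraction (68/93).
#'
#' @param n number of profiles.
#' @param seed integer seed.
#' @return data frame `subject_id`, `height`, `weight`, `age`, `sex` (1 =
#'   male, 0 = female).
#' @export
simulate_profiles <- function(n, seed = 1L) {
  with_seed(seed, {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      height = rtrunc_norm(n, 167.4, 5.2, 158, 180),
      weight = rtrunc_norm(n, 68.8, 10.2, 54, 93),
      age = rtrunc_norm(n, 55.4, 12.1, 22, 83),
      sex = stats::rbinom(n, 1L, 68 / 93),
      stringsAsFactors = FALSE
    )
  })
}

depth_profile <- function(spec, seed) {
  # per-second latent depth with contiguous induction/maintenance/recovery
  t_ind <- seq_len(spec$dur_induction)
  t_mnt <- seq_len(spec$dur_maintenance)
  t_rec <- seq_len(spec$dur_recovery)
  with_seed(seed, {
    # smooth sigmoidal descent / ascent plus a slow AR(1) wander
    sg <- function(u) 1 / (1 + exp(-8 * (u - 0.5)))
    ind <- spec$depth_awake -
      (spec$depth_awake - spec$depth_plateau) * sg(t_ind / spec$dur_induction)
    wander <- stats::filter(stats::rnorm(spec$dur_maintenance, 0, 1.2),
                            0.98, method = "recursive")
    mnt <- spec$depth_plateau + as.numeric(wander)
    rec <- mnt[length(mnt)] +
      (spec$depth_end - mnt[length(mnt)]) * sg(t_rec / spec$dur_recovery)
    depth <- pmin(100, pmax(0, c(ind, mnt, rec)))
    phase <- c(rep("induction", length(ind)),
               rep("maintenance", length(mnt)),
               rep("recovery", length(rec)))
    list(times = seq_along(depth) - 1, depth = depth, phase = phase)
  })
}

#' Simulate one subject
#'
#' Generates the EEG recording and its latent depth trajectory plus the
#' noisy reference series. Fully determined by `seed`.
#'
#' @param profile one row of [simulate_profiles()].
#' @param spec a [generator_spec()].
#' @param seed integer seed for this subject.
#' @return list with `recording` ([raw_recording()]), `trajectory`
#'   (ground-truth [depth_trajectory()]) and `reference` (noisy monitor
#'   [depth_trajectory()]).
#' @export
simulate_subject <- function(profile, spec, seed = 1L) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  dp <- depth_profile(spec, seed)
  fs <- spec$fs
  n <- as.integer(round((length(dp$times)) * fs))
  t_samp <- (seq_len(n) - 1) / fs
  d_samp <- stats::approx(dp$times, dp$depth, xout = t_samp, rule = 2)$y
  d01 <- d_samp / 100
  with_seed(child_seed(seed, 7L), {
    slow <- fft_bandpass(stats::rnorm(n), fs, 0.5, 4)
    fast <- fft_bandpass(stats::rnorm(n), fs, 15, 40)
    mid <- fft_bandpass(stats::rnorm(n), fs, 4, 15)
    eps <- stats::rnorm(n)
    slow <- slow / stats::sd(slow); fast <- fast / stats::sd(fast)
    mid <- mid / stats::sd(mid)
    ratio <- exp(spec$ratio_c0 + spec$ratio_c1 * d01)   # P_fast / P_slow
    p_slow <- 1 / (1 + ratio); p_fast <- ratio / (1 + ratio)
    # slow multiplicative log-gain jitter per band: AR(1) on a 1 s grid,
    # interpolated to sample rate, stationary SD gain_jitter_sd
    jit <- function() {
      if (spec$gain_jitter_sd <= 0) return(rep(1, n))
      n_sec <- length(dp$times)
      innov_sd <- spec$gain_jitter_sd * sqrt(1 - spec$gain_jitter_ar^2)
      g <- as.numeric(stats::filter(stats::rnorm(n_sec, 0, innov_sd),
                                    spec$gain_jitter_ar,
                                    method = "recursive"))
      exp(stats::approx(dp$times, g, xout = t_samp, rule = 2)$y / 2)
    }
    x <- sqrt(p_slow) * jit() * slow + sqrt(p_fast) * jit() * fast +
      sqrt(0.3) * jit() * mid + 0.15 * eps
    # regularity: depth-dependent one-pole smoothing (deeper -> smoother)
    rho <- 0.6 * (1 - d01)
    y <- numeric(n); y[1L] <- x[1L]
    for (i in 2:n) y[i] <- (1 - rho[i]) * x[i] + rho[i] * y[i - 1L]
    y <- y / stats::sd(y) * spec$rms_uV
    ref_noise <- stats::rnorm(length(dp$times), 0, spec$ref_noise_sd)
    list(
      recording = raw_recording(y, fs = fs, subject_id = profile$subject_id),
      trajectory = depth_trajectory(dp$times, dp$depth, dp$phase),
      reference = depth_trajectory(dp$times,
                                   pmin(100, pmax(0, dp$depth + ref_noise)),
                                   dp$phase)
    )
  })
}

#' Simulate a cohort
#'
#' Independent seeded subjects with demographic profiles; the default size
#' (93) matches the clinical cohort layout and splits 61/16/16 with
#' [split_cohort()].
#'
#' @param spec a [generator_spec()].
#' @return list of per-subject lists (`recording`, `trajectory`,
#'   `reference`, `profile`), plus attribute `profiles`.
#' @export
simulate_cohort <- function(spec = generator_spec()) {
  profiles <- simulate_profiles(spec$n_subjects, seed = spec$seed)
  out <- lapply(seq_len(spec$n_subjects), function(i) {
    sub <- simulate_subject(profiles[i, ], spec,
                            seed = child_seed(spec$seed, i))
    sub$profile <- profiles[i, ]
    sub
  })
  names(out) <- profiles$subject_id
  attr(out, "profiles") <- profiles
  out
}
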