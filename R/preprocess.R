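# Raw-signal ingestion, band-pass filtering and epoching.

#' Construct a raw single-channel EEG recording
#'
#' @param samples numeric vector of amplitudes (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id subject identifier.
#' @param start_time recording start in seconds (default 0).
#' @param na_action what to do with NA samples: `"error"` (default) rejects the
#'   recording, `"drop"` removes them (time axis is re-derived from `fs`).
#' @return an object of class `RawRecording`.
#' @export
raw_recording <- function(samples, fs, subject_id = "S1", start_time = 0,
                          na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("`fs` must be a positive sampling rate in Hz")
  if (!is.numeric(samples) || length(samples) == 0L)
    stopf("`samples` must be a nonempty numeric vector")
  if (anyNA(samples)) {
    if (na_action == "error")
      stopf("recording for subject %s contains %d NA samples",
            subject_id, sum(is.na(samples)))
    samples <- samples[!is.na(samples)]
    if (!length(samples)) stopf("recording is all-NA after dropping")
  }
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 subject_id = as.character(subject_id),
                 start_time = as.numeric(start_time)),
            class = "RawRecording")
}

#' @export
print.RawRecording <- function(x, ...) {
  cat(sprintf("<RawRecording> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read a recording from two-column delimited text
#'
#' Expects columns `time_s` and `amplitude_uV` (header optional; any common
#' delimiter). The sampling rate is inferred from the median time step unless
#' given.
#'
#' @param path file path.
#' @param fs optional sampling rate override (Hz).
#' @param subject_id identifier for the recording.
#' @return a [raw_recording()].
#' @export
read_eeg_text <- function(path, fs = NULL, subject_id = "S1") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header, sep = "",
                           comment.char = "#")
  if (ncol(tab) < 2L) {
    # retry with comma delimiter
    tab <- utils::read.table(path, header = has_header, sep = ",",
                             comment.char = "#")
  }
  if (ncol(tab) < 2L)
    stopf("expected 2 columns (time_s, amplitude_uV) in %s", path)
  t <- as.numeric(tab[[1L]]); a <- as.numeric(tab[[2L]])
  if (is.null(fs)) {
    dt <- stats::median(diff(t))
    if (!is.finite(dt) || dt <= 0) stopf("cannot infer fs from time column")
    fs <- 1 / dt
  }
  raw_recording(a, fs = fs, subject_id = subject_id, start_time = t[1L])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the requested order and applies it
#' forward-backward (`signal::filtfilt`), so the output has zero phase shift
#' and epoch timestamps stay aligned with the raw signal.
#'
#' @param rec a [raw_recording()].
#' @param f_lo,f_hi band edges in Hz; must satisfy `0 < f_lo < f_hi < fs/2`.
#' @param order filter order (>= 1); default 4.
#' @return a filtered `RawRecording` of identical length and sampling rate.
#' @export
bandpass_filter <- function(rec, f_lo = 0.5, f_hi = 47, order = 4L) {
  stopifnot(inherits(rec, "RawRecording"))
  nyq <- rec$fs / 2
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq))
    stopf("band [%g, %g] Hz must satisfy 0 < f_lo < f_hi < fs/2 = %g Hz",
          f_lo, f_hi, nyq)
  if (order < 1L) stopf("filter order must be >= 1, got %s", order)
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  if (any(!is.finite(bf$b)) || any(!is.finite(bf$a)) ||
      any(abs(polyroot(rev(bf$a))) >= 1 + 1e-8))
    stopf("Butterworth design unstable at order %d for band [%g, %g] Hz",
          order, f_lo, f_hi)
  y <- signal::filtfilt(bf, rec$samples)
  if (any(!is.finite(y)))
    stopf("filtering produced non-finite output at order %d", order)
  out <- rec
  out$samples <- as.numeric(y)
  out
}

#' Cut a recording into fixed-length epochs
#'
#' Slides a window of `N` samples with `N - overlap` step over the recording;
#' the trailing partial window is discarded. With the defaults (fs = 125 Hz,
#' N = 500) each epoch spans 4 s, the usual update cadence of clinical depth
#' monitors.
#'
#' @param rec a [raw_recording()].
#' @param N epoch length in samples (default 500).
#' @param overlap samples shared by consecutive epochs; `0 <= overlap < N`.
#' @return an `EpochedSignal`: list with `epochs` (list of length-N numeric
#'   vectors), `N`, `fs`, `epoch_times` (start of each epoch, seconds) and
#'   `subject_id`.
#' @export
epoch_signal <- function(rec, N = 500L, overlap = 0L) {
  stopifnot(inherits(rec, "RawRecording"))
  L <- length(rec$samples)
  N <- as.integer(N); overlap <- as.integer(overlap)
  if (N > L)
    stopf("recording has %d samples; at least N = %d required", L, N)
  if (overlap < 0L || overlap >= N)
    stopf("overlap must satisfy 0 <= overlap < N")
  step <- N - overlap
  n_ep <- (L - N) %/% step + 1L
  starts <- (seq_len(n_ep) - 1L) * step
  epochs <- lapply(starts, function(s) rec$samples[(s + 1L):(s + N)])
  structure(list(epochs = epochs, N = N, fs = rec$fs,
                 epoch_times = rec$start_time + starts / rec$fs,
                 subject_id = rec$subject_id),
            class = "EpochedSignal")
}

#' @export
print.EpochedSignal <- function(x, ...) {
  cat(sprintf("<EpochedSignal> subject %s: %d epochs x %d samples @ %g Hz\n",
              x$subject_id, length(x$epochs), x$N, x$fs))
  invisible(x)
}

#' Write / read an epoch table (delimited long format)
#'
#' Long format with columns `epoch_index`, `sample_index`, `value`; the header
#' carries `fs`, `N` and epoch start times as `#`-comment lines so a round
#' trip reproduces the object.
#'
#' @param es an `EpochedSignal`.
#' @param path output path.
#' @return `path` invisibly ([write_epochs()]); an `EpochedSignal`
#'   ([read_epochs()]).
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "EpochedSignal"))
  hdr <- c(sprintf("# fs=%.10g N=%d subject=%s", es$fs, es$N, es$subject_id),
           sprintf("# epoch_times=%s",
                   paste(sprintf("%.10g", es$epoch_times), collapse = ",")))
  tab <- data.frame(
    epoch_index = rep(seq_along(es$epochs), each = es$N),
    sample_index = rep(seq_len(es$N), times = length(es$epochs)),
    value = unlist(es$epochs, use.names = FALSE)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("epoch_index\tsample_index\tvalue", con)
  utils::write.table(format(tab, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  lines <- readLines(path, n = 2L)
  m <- regmatches(lines[1L],
                  regexec("# fs=([0-9.eE+-]+) N=([0-9]+) subject=(.*)", lines[1L]))[[1L]]
  if (length(m) != 4L) stopf("missing epoch-table header in %s", path)
  fs <- as.numeric(m[2L]); N <- as.integer(m[3L]); subject <- m[4L]
  times <- as.numeric(strsplit(sub("# epoch_times=", "", lines[2L]), ",")[[1L]])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  epochs <- split(tab$value, tab$epoch_index)
  epochs <- unname(epochs[order(as.integer(names(epochs)))])
  structure(list(epochs = epochs, N = N, fs = fs,
                 epoch_times = times, subject_id = subject),
            class = "EpochedSignal")
}

#' Construct a reference depth trajectory
#'
#' A BIS-like 0-100 series with contiguous phase labels. 100 means fully
#' awake; values fall through induction, plateau during maintenance and rise
#' in recovery.
#'
#' @param times sample times in seconds.
#' @param depth depth-index values, clipped to \[0, 100\].
#' @param phase character vector of phase labels, one per sample, from
#'   `c("induction", "maintenance", "recovery")`.
#' @return a `DepthTrajectory` data frame.
#' @export
depth_trajectory <- function(times, depth, phase) {
  stopifnot(length(times) == length(depth), length(depth) == length(phase))
  bad <- setdiff(unique(phase), c("induction", "maintenance", "recovery"))
  if (length(bad)) stopf("unknown phase label(s): %s", paste(bad, collapse = ", "))
  depth <- pmin(100, pmax(0, depth))
  # phases must form contiguous blocks in clinical order when all present
  r <- rle(as.character(phase))$values
  if (anyDuplicated(r)) stopf("phase labels must form contiguous blocks")
  structure(data.frame(times = times, depth = depth, phase = phase,
                       stringsAsFactors = FALSE),
            class = c("DepthTrajectory", "data.frame"))
}

#' Look up reference depth at given times
#'
#' Nearest-timestamp join used to pair epochs with the reference series.
#' Times farther than `tolerance` seconds from any reference sample give NA.
#'
#' @param traj a [depth_trajectory()].
#' @param at times (seconds) to query.
#' @param tolerance maximum allowed gap in seconds (default 5).
#' @return data frame with `depth` and `phase` at each query time.
#' @export
depth_at <- function(traj, at, tolerance = 5) {
  idx <- vapply(at, function(tt) which.min(abs(traj$times - tt)), 1L)
  gap <- abs(traj$times[idx] - at)
  depth <- traj$depth[idx]; phase <- traj$phase[idx]
  depth[gap > tolerance] <- NA_real_
  phase[gap > tolerance] <- NA_character_
  data.frame(depth = depth, phase = phase, stringsAsFactors = FALSE)
}
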