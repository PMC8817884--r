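# Minimal EDF (European Data Format) support: continuous 16-bit records,
# enough to round-trip the single-channel recordings this package works with.
# Header layout follows the EDF field widths (ASCII, space-padded).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a single-channel recording to an EDF file
#'
#' Stores `samples` as one EDF signal in 16-bit integers with 1-second data
#' records. The sampling rate must be a whole number of samples per second and
#' the signal is zero-padded to a whole number of records (the true sample
#' count is recoverable from `n_samples` on read when the duration is an
#' integer number of seconds, as all package writers guarantee).
#'
#' @param rec a `RawRecording` (see [raw_recording()]).
#' @param path output file path.
#' @param label EDF signal label (default `"EEG"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, label = "EEG") {
  stopifnot(inherits(rec, "RawRecording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stopf("EDF writer requires an integer sampling rate, got %g", fs)
  fs <- as.integer(round(fs))
  x <- rec$samples
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, rep(0, n_rec * fs - length(x)))

  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ - pmin_ < 1e-12) { pmin_ <- pmin_ - 1; pmax_ <- pmax_ + 1 }
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id %||% "X", 80),
    edf_pad("Startdate 01-JAN-2000", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256L + 256L, 8),            # header bytes: fixed + 1 signal block
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),                    # record duration, seconds
    edf_pad("1", 4)                     # number of signals
  )
  sig <- paste0(
    edf_pad(label, 16), edf_pad("", 80), edf_pad("uV", 8),
    edf_pad(format(pmin_, digits = 7), 8), edf_pad(format(pmax_, digits = 7), 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8), edf_pad("", 80),
    edf_pad(fs, 8), edf_pad("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' Minimal continuous-EDF reader. By default the first signal whose label
#' looks like an EEG channel is selected (any label containing "EEG",
#' case-insensitively, else the first signal); a specific channel can be
#' requested by `channel` (name substring or index).
#'
#' @param path EDF file path.
#' @param channel optional channel name substring or integer index.
#' @param subject_id identifier stored on the returned recording; defaults to
#'   the EDF patient field.
#' @return a [raw_recording()] object.
#' @export
read_edf <- function(path, channel = NULL, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                               # version
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stopf("EDF header has no signals: %s", path)

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)       # transducer
  for (i in seq_len(ns)) rd(8)        # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)       # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  if (is.null(channel)) {
    hit <- grep("EEG", labels, ignore.case = TRUE)
    ch <- if (length(hit)) hit[1L] else 1L
  } else if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > ns) stopf("channel index %d out of range 1..%d", ch, ns)
  } else {
    hit <- grep(channel, labels, ignore.case = TRUE, fixed = FALSE)
    if (!length(hit))
      stopf("no EDF channel matching '%s'; labels: %s", channel,
            paste(labels, collapse = ", "))
    ch <- hit[1L]
  }

  out <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2L,
                      endian = "little", signed = TRUE)
      if (s == ch) out <- c(out, vals)
    }
  }
  phys <- pmin_[ch] + (out - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
    (dmax[ch] - dmin[ch])
  raw_recording(phys, fs = spr[ch] / rec_dur,
                subject_id = subject_id %||% patient)
}
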