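# Assembly of 24x24 feature-image samples from consecutive feature vectors,
# subject-level cohort splitting, and training-split standardization.

IMG_SIDE <- 24L
IMG_LEN <- 576L

#' Flatten / rebuild a 24x24 sample image
#'
#' The 576-vector is laid out row-major: each of the 12 consecutive periods
#' contributes two rows of 24 indicator values (48 per period), oldest period
#' first. `as_sample_image` and `flatten_image` are exact inverses.
#'
#' @param v numeric vector of length 576.
#' @param m a 24x24 numeric matrix.
#' @return a 24x24 matrix / a length-576 vector.
#' @export
as_sample_image <- function(v) {
  if (length(v) != IMG_LEN)
    stopf("sample vector must have exactly %d elements, got %d",
          IMG_LEN, length(v))
  matrix(v, IMG_SIDE, IMG_SIDE, byrow = TRUE)
}

#' @rdname as_sample_image
#' @export
flatten_image <- function(m) {
  if (!is.matrix(m) || any(dim(m) != IMG_SIDE))
    stopf("expected a %dx%d matrix", IMG_SIDE, IMG_SIDE)
  as.vector(t(m))
}

#' Build feature-image samples from a feature table
#'
#' Slides a window of `periods_per_sample` consecutive epochs over each
#' subject's feature table (stride in epochs); the window's indicator values
#' (schema order, oldest period first) are concatenated into one 576-vector
#' and reshaped row-major to a 24x24 image. The regression target is the
#' reference depth at the window's final epoch (causal monitoring). Windows
#' whose target cannot be aligned are dropped.
#'
#' @param feature_table output of [extract_features()] (one or more subjects),
#'   already standardized if a standardizer is in use.
#' @param reference named list of [depth_trajectory()] keyed by subject id.
#' @param periods_per_sample epochs per sample; indicator count x periods
#'   must equal 576 (default 12 x 48).
#' @param stride window stride in epochs (default 1).
#' @param tolerance target alignment tolerance, seconds.
#' @return a `SampleSet`: list with matrix `x` (n x 576, rows are flattened
#'   images), `y` (targets 0-100), `subject_id`, `time`, `phase`.
#' @export
build_samples <- function(feature_table, reference, periods_per_sample = 12L,
                          stride = 1L, tolerance = 5) {
  sc <- feature_schema()
  cols <- sc$name
  miss <- setdiff(cols, names(feature_table))
  if (length(miss)) stopf("feature table lacks schema column(s): %s",
                          paste(miss, collapse = ", "))
  k <- length(cols) * as.integer(periods_per_sample)
  if (k != IMG_LEN)
    stopf("indicator count (%d) x periods_per_sample (%d) must equal %d",
          length(cols), periods_per_sample, IMG_LEN)
  P <- as.integer(periods_per_sample)
  xs <- list(); ys <- numeric(0); sid <- character(0)
  tms <- numeric(0); ph <- character(0)
  for (s in unique(feature_table$subject_id)) {
    rows <- feature_table[feature_table$subject_id == s, , drop = FALSE]
    rows <- rows[order(rows$epoch_time), , drop = FALSE]
    n_ep <- nrow(rows)
    if (n_ep < P) next
    fm <- as.matrix(rows[, cols, drop = FALSE])
    starts <- seq(1L, n_ep - P + 1L, by = stride)
    ref <- reference[[s]]
    for (st in starts) {
      t_end <- rows$epoch_time[st + P - 1L]
      tgt <- if (is.null(ref)) list(depth = NA_real_, phase = NA_character_)
             else depth_at(ref, t_end, tolerance = tolerance)
      if (!is.finite(tgt$depth[1L])) next
      v <- as.vector(t(fm[st:(st + P - 1L), , drop = FALSE]))
      xs[[length(xs) + 1L]] <- v
      ys <- c(ys, tgt$depth[1L]); sid <- c(sid, s)
      tms <- c(tms, t_end); ph <- c(ph, tgt$phase[1L])
    }
  }
  if (!length(xs)) stopf("no samples could be built (check alignment)")
  structure(list(x = do.call(rbind, xs), y = ys, subject_id = sid,
                 time = tms, phase = ph),
            class = "SampleSet")
}

#' @export
print.SampleSet <- function(x, ...) {
  cat(sprintf("<SampleSet> %d samples (24x24) from %d subject(s)\n",
              nrow(x$x), length(unique(x$subject_id))))
  invisible(x)
}

subset_samples <- function(set, idx) {
  structure(list(x = set$x[idx, , drop = FALSE], y = set$y[idx],
                 subject_id = set$subject_id[idx], time = set$time[idx],
                 phase = set$phase[idx]), class = "SampleSet")
}

#' Split a cohort into train / validation / test by subject
#'
#' Seeded uniform random partition without replacement, always at the
#' subject level so no subject's samples leak across splits.
#'
#' @param subject_ids character vector of distinct subject ids.
#' @param sizes integer triple `(train, validation, test)` summing to the
#'   cohort size; default `c(61, 16, 16)`.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return a `CohortSplit`: list with `train`, `validation`, `test` id
#'   vectors and `counts`.
#' @export
split_cohort <- function(subject_ids, sizes = c(61L, 16L, 16L), seed = 1L) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stopf("subject ids must be distinct")
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 0L))
    stopf("sizes must be three nonnegative counts")
  if (sum(sizes) != length(subject_ids))
    stopf("sizes sum to %d but cohort has %d subjects",
          sum(sizes), length(subject_ids))
  perm <- with_seed(seed, sample(subject_ids))
  structure(list(
    train = perm[seq_len(sizes[1L])],
    validation = perm[sizes[1L] + seq_len(sizes[2L])],
    test = perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])],
    counts = sizes
  ), class = "CohortSplit")
}

#' Fit / apply per-indicator standardization
#'
#' Z-scores every schema column using statistics from the training split
#' only; the same statistics are then applied unchanged to validation and
#' test tables. Zero-variance columns are centered but not scaled.
#'
#' @param feature_table training-split feature table.
#' @return a `Standardizer` (named means and SDs).
#' @export
fit_standardizer <- function(feature_table) {
  cols <- feature_schema()$name
  m <- as.matrix(feature_table[, cols, drop = FALSE])
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  structure(list(mean = mu, sd = sdv, columns = cols),
            class = "Standardizer")
}

#' @rdname fit_standardizer
#' @param std a fitted `Standardizer`.
#' @export
apply_standardizer <- function(feature_table, std) {
  stopifnot(inherits(std, "Standardizer"))
  out <- feature_table
  for (j in seq_along(std$columns)) {
    cn <- std$columns[j]
    out[[cn]] <- (out[[cn]] - std$mean[j]) / std$sd[j]
  }
  out
}

#' Write / read a sample store
#'
#' One delimited file per split: metadata columns then the 576 pixel values;
#' the loader validates the 576-element constraint.
#'
#' @param set a `SampleSet`.
#' @param path file path.
#' @return `path` invisibly; [read_samples()] returns a `SampleSet`.
#' @export
write_samples <- function(set, path) {
  stopifnot(inherits(set, "SampleSet"))
  tab <- data.frame(subject_id = set$subject_id, time = set$time,
                    phase = set$phase, target = set$y,
                    stringsAsFactors = FALSE)
  px <- as.data.frame(set$x)
  names(px) <- sprintf("px%03d", seq_len(ncol(px)))
  utils::write.table(cbind(tab, px), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  px_cols <- grep("^px[0-9]+$", names(tab))
  if (length(px_cols) != IMG_LEN)
    stopf("sample store has %d pixel columns; exactly %d required",
          length(px_cols), IMG_LEN)
  structure(list(x = as.matrix(tab[, px_cols]), y = tab$target,
                 subject_id = tab$subject_id, time = tab$time,
                 phase = tab$phase), class = "SampleSet")
}
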