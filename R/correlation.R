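# Correlation-based comparison of candidate depth indices against a
# reference depth series, with the clinical banding rules.

#' Correlation coefficient between two series
#'
#' `cov(x, y) / sqrt(var(x) var(y))` evaluated with population moments, as
#' used to compare a candidate sedation index against a reference depth
#' series. Returns `NA_real_` (undefined) when either series is constant.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return value in \[-1, 1\], or `NA_real_`.
#' @export
correlation <- function(x, y) {
  assert_numeric_vector(x); assert_numeric_vector(y)
  if (length(x) != length(y)) stopf("series lengths differ: %d vs %d",
                                    length(x), length(y))
  if (length(x) < 3L) stopf("need at least 3 paired observations")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  r <- mean((x - mx) * (y - my)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Classify an absolute correlation into a clinical band
#'
#' \eqn{|COR| > 0.8} is high, 0.5-0.8 moderate, 0.3-0.5 low, below 0.3 none.
#' Boundary values fall into the lower band (0.8 is moderate, 0.5 is low,
#' 0.3 is none).
#'
#' @param abs_cor value in \[0, 1\].
#' @return one of `"high"`, `"moderate"`, `"low"`, `"none"`.
#' @export
classify_band <- function(abs_cor) {
  if (!is.numeric(abs_cor) || anyNA(abs_cor) ||
      any(abs_cor < 0 | abs_cor > 1))
    stopf("abs_cor must lie in [0, 1]")
  vapply(abs_cor, function(a) {
    if (a > 0.8) "high" else if (a > 0.5) "moderate"
    else if (a > 0.3) "low" else "none"
  }, "")
}

#' Compare candidate indices against a reference depth series
#'
#' For every index column, computes the per-subject correlation with the
#' reference depth aligned by nearest timestamp, then summarizes
#' `mean(|COR|) +/- SD` across subjects and ranks indices by the mean.
#' Subjects whose epochs cannot be aligned within `tolerance` seconds (or
#' with fewer than 3 aligned points) are skipped with a warning.
#'
#' @param feature_table data frame with `subject_id`, `epoch_time` and index
#'   columns (e.g. from [extract_features()], possibly with a model-output
#'   column appended).
#' @param reference named list of [depth_trajectory()] objects keyed by
#'   subject id.
#' @param indices character vector of columns to compare; defaults to every
#'   non-covariate EEG index in the schema that is present, plus any extra
#'   columns passed explicitly.
#' @param tolerance alignment tolerance in seconds.
#' @return data frame of class `CorrelationResult` with columns `index`,
#'   `mean_abs_cor`, `sd_abs_cor`, `band`, `n_subjects`, ranked by
#'   `mean_abs_cor` (descending); per-subject values in
#'   `attr(, "per_subject")`.
#' @export
index_comparison <- function(feature_table, reference, indices = NULL,
                             tolerance = 5) {
  if (is.null(indices)) {
    sc <- feature_schema()
    indices <- intersect(sc$name[sc$kind == "eeg"], names(feature_table))
  }
  miss <- setdiff(indices, names(feature_table))
  if (length(miss)) stopf("index column(s) not in table: %s",
                          paste(miss, collapse = ", "))
  subjects <- unique(feature_table$subject_id)
  per <- matrix(NA_real_, length(subjects), length(indices),
                dimnames = list(subjects, indices))
  for (s in subjects) {
    traj <- reference[[s]]
    if (is.null(traj)) {
      warning(sprintf("no reference depth for subject %s; skipped", s))
      next
    }
    rows <- feature_table[feature_table$subject_id == s, , drop = FALSE]
    ref <- depth_at(traj, rows$epoch_time, tolerance = tolerance)
    ok <- is.finite(ref$depth)
    if (sum(ok) < 3L) {
      warning(sprintf("subject %s: <3 epochs align with reference; skipped", s))
      next
    }
    for (ix in indices)
      per[s, ix] <- correlation(rows[[ix]][ok], ref$depth[ok])
  }
  mean_abs <- apply(abs(per), 2L, mean, na.rm = TRUE)
  sd_abs <- apply(abs(per), 2L, stats::sd, na.rm = TRUE)
  n_sub <- apply(per, 2L, function(v) sum(is.finite(v)))
  out <- data.frame(index = indices, mean_abs_cor = unname(mean_abs),
                    sd_abs_cor = unname(sd_abs), n_subjects = unname(n_sub),
                    stringsAsFactors = FALSE)
  out$band <- classify_band(pmin(1, pmax(0, ifelse(is.finite(out$mean_abs_cor),
                                                   out$mean_abs_cor, 0))))
  out <- out[order(-out$mean_abs_cor), ]
  rownames(out) <- NULL
  attr(out, "per_subject") <- per
  class(out) <- c("CorrelationResult", "data.frame")
  out
}

#' Write an index-comparison report
#'
#' Tab-delimited table with one row per index: name, mean |COR|, SD and band.
#'
#' @param res an [index_comparison()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cor_report <- function(res, path) {
  tab <- data.frame(
    Index = res$index,
    COR = sprintf("%.3f ± %.2f", res$mean_abs_cor, res$sd_abs_cor),
    Band = res$band, Subjects = res$n_subjects
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
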