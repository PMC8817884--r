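# Goodness-of-fit metrics and the phase-stratified evaluation report.

#' Coefficient of determination
#'
#' `1 - SSE/SST` with `SSE = sum((obs - pred)^2)` and
#' `SST = sum((obs - mean(obs))^2)`. Undefined (NA) when the observed series
#' is constant.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return value <= 1, or `NA_real_`.
#' @export
r_squared <- function(observed, predicted) {
  assert_numeric_vector(observed); assert_numeric_vector(predicted)
  if (length(observed) != length(predicted))
    stopf("lengths differ: %d vs %d", length(observed), length(predicted))
  if (length(observed) < 2L) stopf("need at least 2 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / sst
}

#' Root-mean-squared error
#'
#' `sqrt(mean((obs - pred)^2))`, in the units of the depth index. (The
#' textbook shorthand `sum(e_i - mean(e))/n` sometimes quoted for this
#' quantity is identically zero; the standard definition is implemented.)
#'
#' @inheritParams r_squared
#' @return nonnegative value; 0 iff the vectors are identical.
#' @export
rmse <- function(observed, predicted) {
  assert_numeric_vector(observed); assert_numeric_vector(predicted)
  if (length(observed) != length(predicted))
    stopf("lengths differ: %d vs %d", length(observed), length(predicted))
  sqrt(mean((observed - predicted)^2))
}

#' Mean absolute percentage error
#'
#' `mean(|obs - pred| / obs) * 100`. Undefined when any observed value is
#' zero; the offending indices are reported on the returned NA's
#' `"zero_indices"` attribute.
#'
#' @inheritParams r_squared
#' @return nonnegative percentage, or flagged `NA_real_`.
#' @export
mape <- function(observed, predicted) {
  assert_numeric_vector(observed); assert_numeric_vector(predicted)
  if (length(observed) != length(predicted))
    stopf("lengths differ: %d vs %d", length(observed), length(predicted))
  zero <- which(observed == 0)
  if (length(zero)) {
    out <- NA_real_
    attr(out, "zero_indices") <- zero
    return(out)
  }
  mean(abs(observed - predicted) / abs(observed)) * 100
}

#' Accuracy within a depth tolerance
#'
#' Fraction of predictions within `tol` depth units of the reference, in
#' percent — the regression analogue of a hit rate for a 0-100 depth index.
#'
#' @inheritParams r_squared
#' @param tol tolerance in depth units (default 10).
#' @return percentage in \[0, 100\].
#' @export
accuracy_within <- function(observed, predicted, tol = 10) {
  assert_numeric_vector(observed); assert_numeric_vector(predicted)
  if (length(observed) != length(predicted))
    stopf("lengths differ: %d vs %d", length(observed), length(predicted))
  mean(abs(observed - predicted) <= tol) * 100
}

#' Phase-stratified metrics report
#'
#' Computes R^2 (%), RMSE, MAPE (%), accuracy (%) and n per anesthesia phase
#' (induction, maintenance, recovery) plus an overall row.
#'
#' @inheritParams r_squared
#' @param phases character labels per sample from
#'   `c("induction", "maintenance", "recovery")`.
#' @param tol accuracy tolerance in depth units.
#' @return a `MetricsReport` data frame with rows per phase and `overall`.
#' @export
phase_report <- function(observed, predicted, phases, tol = 10) {
  if (length(phases) != length(observed))
    stopf("phase labels must align with observations")
  known <- c("induction", "maintenance", "recovery")
  bad <- setdiff(unique(phases), known)
  if (length(bad)) stopf("unknown phase label(s): %s",
                         paste(bad, collapse = ", "))
  one <- function(idx) {
    if (length(idx) < 2L)
      return(c(r2 = NA_real_, rmse = NA_real_, mape = NA_real_,
               accuracy = NA_real_, n = length(idx)))
    r2 <- r_squared(observed[idx], predicted[idx])
    mp <- mape(observed[idx], predicted[idx])
    c(r2 = 100 * r2, rmse = rmse(observed[idx], predicted[idx]),
      mape = as.numeric(mp),
      accuracy = accuracy_within(observed[idx], predicted[idx], tol),
      n = length(idx))
  }
  present <- known[known %in% phases]
  rows <- lapply(present, function(p) one(which(phases == p)))
  rows <- c(rows, list(one(seq_along(observed))))
  out <- as.data.frame(do.call(rbind, rows))
  out$phase <- c(present, "overall")
  out <- out[, c("phase", "r2", "rmse", "mape", "accuracy", "n")]
  class(out) <- c("MetricsReport", "data.frame")
  out
}

#' Write a metrics report
#'
#' Tab-delimited machine-readable table plus a human-readable block using
#' the clinical row labels ("Induction period", ..., "Whole paragraph").
#'
#' @param report a [phase_report()] result.
#' @param path output path (a `.txt` companion gets the pretty block).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  labels <- c(induction = "Induction period",
              maintenance = "Maintenance period",
              recovery = "Recovery period", overall = "Whole paragraph")
  pretty <- sprintf("%-20s R2(%%)=%6.2f  RMSE=%5.2f  MAPE(%%)=%6.2f  Acc(%%)=%6.2f  n=%d",
                    labels[report$phase], report$r2, report$rmse,
                    report$mape, report$accuracy, report$n)
  writeLines(pretty, paste0(path, ".txt"))
  invisible(path)
}
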