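#' Root-mean-square forecast error
#'
#' `sqrt(mean((pred - actual)^2))` in mg/dL, over paired points where
#' `pred[t]` was issued one prediction horizon before `actual[t]` was
#' observed.
#'
#' @param pred Forecast glucose, mg/dL.
#' @param actual Observed glucose, mg/dL.
#' @return RMSE in mg/dL.
#' @export
bg_rmse <- function(pred, actual) {
  if (length(pred) != length(actual))
    stopf("pred (%d) and actual (%d) differ in length",
          length(pred), length(actual))
  if (!length(pred)) stopf("RMSE of empty series is undefined")
  sqrt(mean((pred - actual)^2))
}

#' Mean absolute relative difference
#'
#' `mean(|pred - actual| / actual) * 100`, the standard CGM accuracy
#' statistic, in percent. Errors on any non-positive actual value rather
#' than silently skipping it.
#'
#' @inheritParams bg_rmse
#' @return MARD in percent.
#' @export
bg_mard <- function(pred, actual) {
  if (length(pred) != length(actual))
    stopf("pred (%d) and actual (%d) differ in length",
          length(pred), length(actual))
  if (!length(pred)) stopf("MARD of empty series is undefined")
  if (any(actual <= 0)) stopf("MARD undefined: actual values must be > 0")
  mean(abs((pred - actual) / actual)) * 100
}

#' Cross-correlation time lag of a forecast
#'
#' The delay at which the forecast best matches the observed series: the
#' Pearson correlation of the overlapping segments is computed at every
#' integer shift `delta` in `[0, max_lag_slots]` (a forecast cannot lead its
#' target), pairing `pred[t + delta]` with `actual[t]`; the integer arg-max
#' is refined to sub-slot resolution by parabolic interpolation through the
#' peak and its neighbours, and returned in minutes. Pearson correlation
#' (rather than raw cross-correlation) makes the arg-max scale free, so
#' amplitude cannot masquerade as delay.
#'
#' @inheritParams bg_rmse
#' @param max_lag_slots Largest shift searched, slots (default 6 = the 30-min
#'   horizon).
#' @param slot_min Minutes per slot (default 5).
#' @return Time lag in minutes (fractional).
#' @export
bg_time_lag <- function(pred, actual, max_lag_slots = 6L, slot_min = SLOT_MIN) {
  if (length(pred) != length(actual))
    stopf("pred (%d) and actual (%d) differ in length",
          length(pred), length(actual))
  N <- length(pred)
  if (N < max_lag_slots + 3L)
    stopf("series too short for a lag search over %d slots", max_lag_slots)
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0)
    stopf("time lag undefined for a constant series")
  shifts <- 0:max_lag_slots
  r <- vapply(shifts, function(d) {
    a <- pred[(1 + d):N]
    b <- actual[1:(N - d)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (all(is.na(r))) stopf("time lag undefined: degenerate overlap")
  k <- which.max(r)
  lag <- shifts[k]
  if (k > 1L && k < length(r) && !anyNA(r[(k - 1L):(k + 1L)])) {
    y1 <- r[k - 1L]; y2 <- r[k]; y3 <- r[k + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) lag <- lag + 0.5 * (y1 - y3) / denom
  }
  lag * slot_min
}

#' Paired comparison of two methods
#'
#' Two-sided paired t-test on per-subject metric vectors (same subjects,
#' same order). Zero-variance differences are a degenerate case: reported
#' with `p_value = 1` and `degenerate = TRUE` instead of erroring
#' mid-pipeline.
#'
#' @param metric_a,metric_b Equal-length paired numeric vectors, `n >= 2`.
#' @return `list(statistic, p_value, df, degenerate)`.
#' @export
compare_methods <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stopf("paired vectors differ in length")
  if (length(metric_a) < 2L) stopf("paired t-test needs n >= 2")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0)
    return(list(statistic = NA_real_, p_value = 1,
                df = length(d) - 1L, degenerate = TRUE))
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Evaluate one forecast series
#'
#' @inheritParams bg_time_lag
#' @return One-row `data.frame(rmse, mard, time_lag)` (mg/dL, %, minutes).
#' @export
evaluate_forecasts <- function(pred, actual, max_lag_slots = 6L) {
  data.frame(rmse = bg_rmse(pred, actual),
             mard = bg_mard(pred, actual),
             time_lag = bg_time_lag(pred, actual, max_lag_slots))
}

#' Aggregate a per-subject metrics table into a report
#'
#' Takes a long table with columns `method`, `subject`, `rmse`, `mard`,
#' `time_lag` and produces the aggregate mean ± SD per method plus pairwise
#' paired t-test p-values of every method against `reference` for each
#' metric.
#'
#' @param metrics Long-format `data.frame` as above.
#' @param reference Method the others are compared against (default
#'   `"drnn"`).
#' @return A `metrics_report`: `list(per_subject, aggregate, p_values)`.
#' @export
metrics_report <- function(metrics, reference = "drnn") {
  need <- c("method", "subject", "rmse", "mard", "time_lag")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stopf("metrics table missing columns: %s",
                          paste(miss, collapse = ", "))
  methods <- unique(metrics$method)
  agg <- do.call(rbind, lapply(methods, function(m) {
    sub <- metrics[metrics$method == m, ]
    data.frame(method = m,
               rmse_mean = mean(sub$rmse), rmse_sd = stats::sd(sub$rmse),
               mard_mean = mean(sub$mard), mard_sd = stats::sd(sub$mard),
               lag_mean = mean(sub$time_lag), lag_sd = stats::sd(sub$time_lag))
  }))
  pvals <- NULL
  if (reference %in% methods && length(methods) > 1L) {
    ref <- metrics[metrics$method == reference, ]
    ref <- ref[order(ref$subject), ]
    pvals <- do.call(rbind, lapply(setdiff(methods, reference), function(m) {
      oth <- metrics[metrics$method == m, ]
      oth <- oth[order(oth$subject), ]
      row <- data.frame(method = m)
      for (col in c("rmse", "mard", "time_lag")) {
        cmp <- compare_methods(ref[[col]], oth[[col]])
        row[[paste0(col, "_p")]] <- cmp$p_value
      }
      row
    }))
  }
  structure(list(per_subject = metrics, aggregate = agg, p_values = pvals,
                 reference = reference),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Forecast performance (mean ± SD over subjects)\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-6s RMSE %5.1f ± %4.1f mg/dL   MARD %5.1f ± %4.1f %%   lag %5.1f ± %4.1f min\n",
                a$method[i], a$rmse_mean[i], a$rmse_sd[i],
                a$mard_mean[i], a$mard_sd[i], a$lag_mean[i], a$lag_sd[i]))
  if (!is.null(x$p_values)) {
    cat(sprintf("Paired t-tests vs %s (p-values):\n", x$reference))
    print(x$p_values, row.names = FALSE)
  }
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report A [metrics_report()].
#' @param path_base Base path; `<base>_per_subject.csv`,
#'   `<base>_aggregate.csv` and `<base>.json` are written.
#' @return `path_base`, invisibly.
#' @export
write_report <- function(report, path_base) {
  utils::write.csv(report$per_subject,
                   paste0(path_base, "_per_subject.csv"), row.names = FALSE)
  utils::write.csv(report$aggregate,
                   paste0(path_base, "_aggregate.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_subject = report$per_subject, aggregate = report$aggregate,
         p_values = report$p_values, reference = report$reference),
    paste0(path_base, ".json"), digits = NA, auto_unbox = TRUE,
    dataframe = "rows", null = "null")
  invisible(path_base)
}
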