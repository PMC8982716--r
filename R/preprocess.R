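#' Detect maximal runs of invalid glucose
#'
#' A slot counts as invalid when its mask is `FALSE` or its glucose reading is
#' missing or non-positive (literal 0 readings are the clinical convention for
#' a sensor outage). Returns the maximal runs as a gap list.
#'
#' @param series A [subject_series()].
#' @return A `data.frame` with columns `start` (first invalid slot, 1-based)
#'   and `length` (slots); zero rows when the series is fully valid.
#' @export
detect_gaps <- function(series) {
  if (!inherits(series, "subject_series")) stopf("`series` must be a subject_series")
  bad <- !series$valid | is.na(series$glucose) | series$glucose <= 0
  true_runs(bad)
}

#' Fill short gaps by first-order interpolation
#'
#' Training-time gap filling: every interior gap of at most `max_gap_slots`
#' slots is replaced by the straight line between the valid samples bounding
#' it, and those slots are marked valid. Longer gaps, and gaps touching the
#' series boundary (no bounding sample on one side), are left untouched; the
#' windowing stage treats them as segment breaks. Intended for training data
#' only — test-time filling must be causal, see [extrapolate_forward()].
#'
#' @param series A [subject_series()].
#' @param max_gap_slots Largest gap (slots) that will be filled; default 24
#'   slots = 2 h.
#' @return The series with short interior gaps filled. Attribute `"filled"`
#'   lists the filled slot indices.
#' @export
fill_gaps_linear <- function(series, max_gap_slots = 24L) {
  if (!is_count(max_gap_slots, min = 0L)) stopf("`max_gap_slots` must be a count")
  gaps <- detect_gaps(series)
  filled <- integer(0)
  n <- series$n_slots
  if (nrow(gaps)) for (i in seq_len(nrow(gaps))) {
    s <- gaps$start[i]; len <- gaps$length[i]
    lo <- s - 1L; hi <- s + len
    if (len > max_gap_slots || lo < 1L || hi > n) next
    g0 <- series$glucose[lo]; g1 <- series$glucose[hi]
    series$glucose[s:(s + len - 1L)] <-
      g0 + (g1 - g0) * seq_len(len) / (len + 1)
    series$valid[s:(s + len - 1L)] <- TRUE
    filled <- c(filled, s:(s + len - 1L))
  }
  attr(series, "filled") <- filled
  series
}

# Shrinking-window running median of a plain numeric vector: at position i the
# window is the largest symmetric window of half-width <= (w-1)/2 that fits.
running_median <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    stats::median(x[(i - k):(i + k)])
  }, numeric(1))
}

#' Median-filter the glucose channel
#'
#' Centered running median with an odd window, applied independently to every
#' contiguous run of valid slots (gaps are never bridged). Window shrinkage at
#' run edges keeps the window symmetric, so the first and last samples pass
#' through unchanged. Removes 1-2 slot spikes while leaving monotone segments
#' intact. Training-time only, like [fill_gaps_linear()].
#'
#' @param series A [subject_series()].
#' @param window_slots Odd window length in slots; default 5 (25 min).
#' @return The series with filtered glucose; only the glucose channel changes.
#' @export
median_filter_series <- function(series, window_slots = 5L) {
  if (!is_count(window_slots) || window_slots %% 2L == 0L)
    stopf("`window_slots` must be an odd positive integer")
  runs <- true_runs(series$valid & !is.na(series$glucose) & series$glucose > 0)
  if (nrow(runs)) for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:(runs$start[i] + runs$length[i] - 1L)
    series$glucose[idx] <- running_median(series$glucose[idx], window_slots)
  }
  series
}

#' Causal linear extrapolation of missing glucose
#'
#' Test-time gap filling: future samples are unknown, so missing values are
#' estimated from the least-squares line through the last `k` valid samples
#' of the history (the recent trend). With fewer than 2 valid trailing
#' samples the last value is held and the result is flagged.
#'
#' @param history Numeric glucose history (mg/dL), most recent last; `NA`
#'   marks invalid samples.
#' @param n_missing Number of future values to estimate.
#' @param k Number of trailing valid samples defining the trend (default 6 =
#'   30 min); fewer are used if the history is shorter.
#' @return Numeric vector of `n_missing` estimates for the slots following
#'   the history. Attribute `"fallback"` is `TRUE` when the hold-last-value
#'   fallback was used.
#' @export
extrapolate_forward <- function(history, n_missing, k = 6L) {
  if (!is_count(n_missing, min = 0L)) stopf("`n_missing` must be a count")
  if (n_missing == 0L) return(numeric(0))
  ok <- which(!is.na(history))
  if (length(ok) == 0L) stopf("history contains no valid samples")
  m <- length(history)
  if (length(ok) < 2L) {
    out <- rep(history[ok[length(ok)]], n_missing)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  use <- utils::tail(ok, k)
  t_obs <- use                       # slot index as the time axis
  y_obs <- history[use]
  fit <- stats::lm.fit(cbind(1, t_obs), y_obs)
  beta <- fit$coefficients
  t_new <- m + seq_len(n_missing)
  out <- as.numeric(beta[1] + beta[2] * t_new)
  attr(out, "fallback") <- FALSE
  out
}

#' Time-of-day index channel
#'
#' Normalizes the 288-slot day into `[0, 1)`: midnight maps to 0, noon to
#' 0.5, 23:55 to 287/288.
#'
#' @param timestamp `POSIXct` timestamps on the 5-minute grid.
#' @return Numeric fraction(s) in `[0, 1)`.
#' @export
time_index <- function(timestamp) {
  if (!inherits(timestamp, "POSIXct")) stopf("`timestamp` must be POSIXct")
  lt <- as.POSIXlt(timestamp, tz = attr(timestamp, "tzone") %||% "UTC")
  secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
  if (any(secs %% (60 * SLOT_MIN) != 0))
    stopf("timestamp is not on the 5-min grid")
  (secs / (60 * SLOT_MIN)) / SLOTS_PER_DAY
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine a target subject with donor subjects for transfer learning
#'
#' Builds the phase-1 training corpus: the whole target record forms the
#' first half, and five donors contribute 10% of the combined corpus each
#' (20% of the target length), taken as that donor's final contiguous block.
#' The pieces are returned as separate series so that downstream windowing
#' never crosses a subject boundary.
#'
#' @param target The target [subject_series()].
#' @param donors List of donor [subject_series()] (normally 5).
#' @return A list of series: the target followed by one block per donor. The
#'   total length is `2 * length(target)` (up to integer rounding of the
#'   per-donor share).
#' @export
build_transfer_corpus <- function(target, donors) {
  if (!inherits(target, "subject_series")) stopf("`target` must be a subject_series")
  if (!length(donors)) stopf("at least one donor is required")
  share <- round(target$n_slots / length(donors))
  blocks <- lapply(donors, function(d) {
    if (!inherits(d, "subject_series")) stopf("donors must be subject_series")
    if (d$n_slots < share)
      stopf("donor '%s' too short: %d slots available, %d required",
            d$subject_id, d$n_slots, share)
    slice_series(d, d$n_slots - share + 1L, d$n_slots)
  })
  c(list(target), blocks)
}

#' Standard training-time preprocessing
#'
#' Convenience wrapper: interpolate short gaps, then median-filter, in that
#' order (both corrections target the same training record). Optionally
#' writes a JSON-lines log with one record per altered slot.
#'
#' @param series A [subject_series()].
#' @param max_gap_slots Passed to [fill_gaps_linear()].
#' @param window_slots Passed to [median_filter_series()].
#' @param log_path Optional path for a JSON-lines preprocessing log.
#' @return The preprocessed series.
#' @export
preprocess_series <- function(series, max_gap_slots = 24L, window_slots = 5L,
                              log_path = NULL) {
  before <- series$glucose
  filled <- fill_gaps_linear(series, max_gap_slots)
  out <- median_filter_series(filled, window_slots)
  if (!is.null(log_path)) {
    con <- file(log_path, open = "wt")
    on.exit(close(con))
    fs <- attr(filled, "filled") %||% integer(0)
    for (s in fs)
      writeLines(jsonlite::toJSON(list(
        op = "interpolate", slot = s,
        time = format(series$time[s], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        value = out$glucose[s]), auto_unbox = TRUE), con)
    changed <- which(filled$valid & !is.na(filled$glucose) &
                       abs(out$glucose - filled$glucose) > 1e-12)
    for (s in changed)
      writeLines(jsonlite::toJSON(list(
        op = "median_filter", slot = s,
        time = format(series$time[s], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        before = filled$glucose[s], value = out$glucose[s]),
        auto_unbox = TRUE), con)
  }
  out
}
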