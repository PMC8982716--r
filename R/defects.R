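# Clinical-style defect injectors. Real CGM records carry dropped intervals,
# additive spikes and frozen readings; these operators reproduce them on
# simulated series so the preprocessing stages can be exercised end to end.

# Resolve a gap start given either the slot index of the last valid sample or
# its timestamp. The gap convention is "strictly after `start` through
# `start + length` slots": a gap quoted as lying between 17:10 and 18:00
# invalidates the 10 slots 17:15, 17:20, ..., 18:00.
resolve_start_slot <- function(series, start) {
  if (inherits(start, "POSIXct")) {
    i <- match(as.numeric(start), as.numeric(series$time))
    if (is.na(i)) stopf("gap start %s not on the series grid",
                        format(start, tz = "UTC"))
    return(i)
  }
  if (!is_count(start, min = 0L)) stopf("gap start must be a slot or POSIXct")
  as.integer(start)
}

#' Invalidate requested intervals of a series
#'
#' Marks the requested slots invalid (sensor dropout). Each gap covers the
#' `gap_lengths[i]` slots strictly after `gap_starts[i]`, where a start is
#' given either as the timestamp (or slot index) of the last valid sample
#' before the gap. Bolus and meal channels are untouched; glucose at the
#' invalidated slots is retained (the reading existed, it is simply flagged),
#' matching a masked-outage convention.
#'
#' @param series A [subject_series()].
#' @param gap_starts List/vector of `POSIXct` timestamps or slot indices.
#' @param gap_lengths Integer slot counts, same length as `gap_starts`.
#' @param seed Unused for explicit gap lists; kept so random defect policies
#'   share one signature.
#' @return The series with `valid` set `FALSE` exactly on the requested slots.
#' @export
inject_missingness <- function(series, gap_starts, gap_lengths, seed = NULL) {
  if (!inherits(series, "subject_series")) stopf("`series` must be a subject_series")
  if (inherits(gap_starts, "POSIXct")) gap_starts <- as.list(gap_starts)
  if (length(gap_starts) != length(gap_lengths))
    stopf("gap_starts and gap_lengths must have equal length")
  n <- series$n_slots
  hit <- logical(n)
  for (i in seq_along(gap_starts)) {
    len <- gap_lengths[[i]]
    if (!is_count(len)) stopf("gap lengths must be positive integers")
    s0 <- resolve_start_slot(series, gap_starts[[i]])
    idx <- (s0 + 1L):(s0 + len)
    if (s0 + len > n || s0 < 0L)
      stopf("gap %d (start slot %d, length %d) exceeds the series extent",
            i, s0, len)
    if (any(hit[idx])) stopf("gap %d overlaps an earlier gap", i)
    hit[idx] <- TRUE
  }
  series$valid[hit] <- FALSE
  series
}

#' Add additive glucose spikes at random valid slots
#'
#' Each valid slot is independently perturbed with probability `rate` by a
#' `N(0, magnitude_sd^2)` additive spike; the result is clipped from below at
#' 1 mg/dL so glucose stays positive. The perturbed slots and their stored
#' spike amounts (after clipping) are attached as attribute `"spikes"`.
#'
#' @param series A [subject_series()].
#' @param rate Fraction of valid slots to perturb, in `[0, 1]`.
#' @param magnitude_sd Spike SD in mg/dL (>= 0).
#' @param seed Integer seed; positions and amounts are reproducible.
#' @return The perturbed series, with a `"spikes"` attribute
#'   (`data.frame(slot, amount)`).
#' @export
inject_outliers <- function(series, rate, magnitude_sd, seed = 1L) {
  if (!inherits(series, "subject_series")) stopf("`series` must be a subject_series")
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stopf("`rate` must be in [0, 1]")
  if (magnitude_sd < 0) stopf("`magnitude_sd` must be >= 0")
  vslots <- which(series$valid)
  with_seed(seed, {
    flag <- stats::runif(length(vslots)) < rate
    slots <- vslots[flag]
    amounts <- stats::rnorm(length(slots), 0, magnitude_sd)
    new_g <- pmax(series$glucose[slots] + amounts, 1)
    amounts <- new_g - series$glucose[slots]   # store post-clip deltas
    series$glucose[slots] <- new_g
    attr(series, "spikes") <- data.frame(slot = slots, amount = amounts)
    series
  })
}

#' Freeze the sensor over an interval
#'
#' Reproduces the recording artefact in which a CGM transmits a constant
#' value: the glucose over `duration_slots` slots strictly after `start` is
#' replaced by the last reading before the interval. Slots remain flagged
#' valid (the defect is undetectable from the mask, as in real exports).
#'
#' @param series A [subject_series()].
#' @param start Timestamp or slot index of the last true reading.
#' @param duration_slots Number of frozen slots (default 24 = 2 h).
#' @return The series with the frozen interval.
#' @export
inject_frozen_sensor <- function(series, start, duration_slots = 24L) {
  if (!is_count(duration_slots)) stopf("`duration_slots` must be a count")
  s0 <- resolve_start_slot(series, start)
  if (s0 < 1L || s0 + duration_slots > series$n_slots)
    stopf("frozen interval exceeds the series extent")
  series$glucose[(s0 + 1L):(s0 + duration_slots)] <- series$glucose[s0]
  series
}
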