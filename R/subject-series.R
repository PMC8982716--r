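#' Multi-channel CGM record for one subject
#'
#' A `subject_series` holds one subject's continuous glucose monitor record on
#' a strict 5-minute grid, together with the insulin-bolus and meal channels
#' and a validity mask. It is the common currency of the whole pipeline: the
#' simulator produces it, the preprocessing operators transform it, and the
#' windowing stage consumes it.
#'
#' @param subject_id Character label for the subject.
#' @param time `POSIXct` timestamps, strictly increasing on a 5-minute grid.
#' @param glucose Glucose concentration in mg/dL per slot; `NA` where invalid.
#' @param bolus Insulin bolus in units delivered at each slot (0 when none).
#' @param meal Meal carbohydrate in grams at each slot (0 when none).
#' @param valid Logical per slot; `FALSE` marks missing or invalid readings.
#'
#' @return An object of class `subject_series`: a list with the six fields
#'   above plus `n_slots`.
#'
#' @details Invariants enforced at construction: equal channel lengths, exact
#'   5-minute spacing, and `glucose > 0` wherever `valid` is `TRUE`. Glucose
#'   at invalid slots may be `NA` (a dropped reading) or a recorded artefact
#'   value (a literal 0 from a sensor outage is mapped to invalid on file
#'   input, see [read_subject_csv()]).
#'
#' @examples
#' t0 <- as.POSIXct("2024-01-01 00:00", tz = "UTC")
#' s <- subject_series("demo", t0 + 300 * (0:11), glucose = rep(120, 12),
#'                     bolus = numeric(12), meal = numeric(12))
#' s
#' @export
subject_series <- function(subject_id, time, glucose, bolus = NULL,
                           meal = NULL, valid = NULL) {
  n <- length(time)
  if (is.null(bolus)) bolus <- numeric(n)
  if (is.null(meal)) meal <- numeric(n)
  if (is.null(valid)) valid <- !is.na(glucose)
  if (!inherits(time, "POSIXct")) stopf("`time` must be POSIXct")
  if (length(glucose) != n || length(bolus) != n || length(meal) != n ||
      length(valid) != n)
    stopf("channel lengths differ: time %d, glucose %d, bolus %d, meal %d, valid %d",
          n, length(glucose), length(bolus), length(meal), length(valid))
  if (n >= 2) {
    dt <- diff(as.numeric(time))
    if (any(abs(dt - 60 * SLOT_MIN) > 1e-6))
      stopf("timestamps must lie on a strictly increasing 5-min grid")
  }
  if (any(valid & (is.na(glucose) | glucose <= 0)))
    stopf("glucose must be > 0 wherever valid")
  structure(
    list(subject_id = as.character(subject_id), time = time,
         glucose = as.numeric(glucose), bolus = as.numeric(bolus),
         meal = as.numeric(meal), valid = as.logical(valid),
         n_slots = n),
    class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  n <- x$n_slots
  nv <- sum(x$valid)
  cat(sprintf("subject_series '%s': %d slots (%.1f days), %d valid (%.1f%%)\n",
              x$subject_id, n, n / SLOTS_PER_DAY, nv, 100 * nv / max(n, 1)))
  if (nv > 0)
    cat(sprintf("  glucose [mg/dL]: median %.0f, range [%.0f, %.0f]\n",
                stats::median(x$glucose[x$valid]),
                min(x$glucose[x$valid]), max(x$glucose[x$valid])))
  cat(sprintf("  events: %d boluses (%.1f U total), %d meals (%.0f g total)\n",
              sum(x$bolus > 0), sum(x$bolus), sum(x$meal > 0), sum(x$meal)))
  invisible(x)
}

#' @export
length.subject_series <- function(x) x$n_slots

# Contiguous sub-series by slot index (keeps the grid invariant).
slice_series <- function(series, from, to) {
  idx <- from:to
  subject_series(series$subject_id, series$time[idx], series$glucose[idx],
                 series$bolus[idx], series$meal[idx], series$valid[idx])
}

#' Write / read a subject series as CSV
#'
#' The on-disk schema has columns `timestamp` (ISO 8601, UTC),
#' `glucose_mgdl`, `bolus_units`, `meal_carbs_g`, `valid` (0/1). Invalid
#' glucose is written as an empty field with `valid = 0`. On input, a literal
#' glucose reading of 0 (the clinical convention for a sensor outage) is
#' accepted and mapped to an invalid slot.
#'
#' @param series A [subject_series()].
#' @param path File path.
#' @param subject_id Subject label for the series read back.
#' @return `write_subject_csv` returns `path` invisibly; `read_subject_csv`
#'   returns a [subject_series()].
#' @export
write_subject_csv <- function(series, path) {
  g <- ifelse(series$valid, series$glucose, NA_real_)
  df <- data.frame(
    timestamp = format(series$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    glucose_mgdl = g,
    bolus_units = series$bolus,
    meal_carbs_g = series$meal,
    valid = as.integer(series$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subject_csv
#' @export
read_subject_csv <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "glucose_mgdl", "bolus_units", "meal_carbs_g", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("CSV missing columns: %s", paste(miss, collapse = ", "))
  tm <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(tm))
    tm <- as.POSIXct(df$timestamp, tz = "UTC")
  g <- as.numeric(df$glucose_mgdl)
  valid <- df$valid != 0 & !is.na(g) & g > 0   # literal 0 readings -> invalid
  g[!valid] <- ifelse(is.na(g[!valid]) | g[!valid] <= 0, NA_real_, g[!valid])
  if (is.null(subject_id))
    subject_id <- sub("\\.csv$", "", basename(path))
  subject_series(subject_id, tm, g, as.numeric(df$bolus_units),
                 as.numeric(df$meal_carbs_g), valid)
}

#' Read an OhioT1DM-style XML export
#'
#' Maps an XML file with `<glucose_level>`, `<bolus>` and `<meal>` event lists
#' (each event an element with `ts` and `value`/`dose`/`carbs` attributes)
#' onto the 5-minute [subject_series()] grid. Glucose readings are snapped to
#' the nearest grid slot; bolus and meal events are accumulated at their slot.
#' Slots without a glucose reading are marked invalid. Requires the `xml2`
#' package. Real OhioT1DM data is distributed under a data-use agreement and
#' is not required by any other part of this package.
#'
#' @param path XML file path.
#' @param subject_id Subject label; defaults to the file name.
#' @param ts_format Timestamp format used in the file.
#' @return A [subject_series()].
#' @export
read_ohio_xml <- function(path, subject_id = NULL,
                          ts_format = "%d-%m-%Y %H:%M:%S") {
  if (!requireNamespace("xml2", quietly = TRUE))
    stopf("read_ohio_xml() requires the 'xml2' package")
  doc <- xml2::read_xml(path)
  get_events <- function(xpath, value_attrs) {
    nodes <- xml2::xml_find_all(doc, xpath)
    if (!length(nodes)) return(data.frame(ts = as.POSIXct(character(), tz = "UTC"),
                                          value = numeric()))
    ts <- as.POSIXct(xml2::xml_attr(nodes, "ts"), format = ts_format, tz = "UTC")
    val <- rep(NA_real_, length(nodes))
    for (a in value_attrs) {
      v <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, a)))
      val[is.na(val)] <- v[is.na(val)]
    }
    data.frame(ts = ts, value = val)
  }
  glu <- get_events(".//glucose_level/event", "value")
  bol <- get_events(".//bolus/event", c("dose", "value"))
  mea <- get_events(".//meal/event", c("carbs", "value"))
  if (!nrow(glu)) stopf("no <glucose_level> events in %s", path)
  grid_sec <- 60 * SLOT_MIN
  snap <- function(ts) round(as.numeric(ts) / grid_sec) * grid_sec
  t0 <- min(snap(glu$ts)); t1 <- max(snap(glu$ts))
  tm <- as.POSIXct(seq(t0, t1, by = grid_sec), tz = "UTC",
                   origin = "1970-01-01")
  n <- length(tm)
  slot_of <- function(ts) as.integer((snap(ts) - t0) / grid_sec) + 1L
  g <- rep(NA_real_, n)
  g[slot_of(glu$ts)] <- glu$value
  acc <- function(ev) {
    out <- numeric(n)
    if (nrow(ev)) {
      sl <- slot_of(ev$ts)
      ok <- sl >= 1 & sl <= n & !is.na(ev$value)
      for (i in which(ok)) out[sl[i]] <- out[sl[i]] + ev$value[i]
    }
    out
  }
  valid <- !is.na(g) & g > 0
  g[!valid] <- NA_real_
  if (is.null(subject_id)) subject_id <- sub("\\.xml$", "", basename(path))
  subject_series(subject_id, tm, g, acc(bol), acc(mea), valid)
}
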