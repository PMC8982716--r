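#' Sliding supervised windows with the [G, I, M, T] channel layout
#'
#' Converts one preprocessed series (or a list of series, e.g. a transfer
#' corpus) into supervised windows. Each window holds `seq_len` consecutive
#' slots of the four channels — glucose (mg/dL), insulin bolus (U), meal
#' carbohydrate (g) and the time-of-day index — and is labelled with the
#' glucose change over the forecast horizon:
#' `label = glucose(t + horizon) - glucose(t)` where `t` is the last window
#' slot. Windows slide with stride 1 and never span an invalid slot or a
#' series boundary, so every contiguous valid segment of length `len`
#' contributes `max(0, len - seq_len - horizon + 1)` windows.
#'
#' @param series A [subject_series()] or a list of them.
#' @param seq_len Window length in slots (default 12 = 60 min of history).
#' @param horizon_slots Forecast horizon in slots (default 6 = 30 min).
#' @return A `window_set`: list with `inputs` (array `n x seq_len x 4`,
#'   channels `G`, `I`, `M`, `T`), `labels` (ΔBG, mg/dL), `x_T` (glucose at
#'   the window end, mg/dL), `anchors` (`data.frame(subject_id, slot, time)`
#'   of the window-end slot), `seq_len`, `horizon`, and `scaler` (`NULL`
#'   until [fit_scaler()]). A series shorter than `seq_len + horizon_slots`
#'   yields an empty set.
#' @export
make_windows <- function(series, seq_len = 12L, horizon_slots = 6L) {
  if (inherits(series, "subject_series")) series <- list(series)
  if (!is_count(seq_len) || !is_count(horizon_slots))
    stopf("`seq_len` and `horizon_slots` must be positive integers")
  pieces <- list()
  for (s in series) {
    if (!inherits(s, "subject_series")) stopf("inputs must be subject_series")
    ok <- s$valid & !is.na(s$glucose) & s$glucose > 0
    runs <- true_runs(ok)
    if (!nrow(runs)) next
    tidx <- time_index(s$time)
    for (r in seq_len(nrow(runs))) {
      len <- runs$length[r]
      nw <- len - seq_len - horizon_slots + 1L
      if (nw < 1L) next
      off <- runs$start[r] - 1L
      # window i covers slots off + i .. off + i + seq_len - 1
      starts <- off + seq_len(nw)
      ends <- starts + seq_len - 1L
      X <- array(0, dim = c(nw, seq_len, 4L))
      for (j in seq_len(seq_len)) {
        sl <- starts + j - 1L
        X[, j, 1L] <- s$glucose[sl]
        X[, j, 2L] <- s$bolus[sl]
        X[, j, 3L] <- s$meal[sl]
        X[, j, 4L] <- tidx[sl]
      }
      labels <- s$glucose[ends + horizon_slots] - s$glucose[ends]
      pieces[[length(pieces) + 1L]] <- list(
        X = X, labels = labels, x_T = s$glucose[ends],
        anchors = data.frame(subject_id = s$subject_id, slot = ends,
                             time = s$time[ends]))
    }
  }
  if (!length(pieces)) {
    ws <- list(inputs = array(0, dim = c(0L, seq_len, 4L)),
               labels = numeric(0), x_T = numeric(0),
               anchors = data.frame(subject_id = character(),
                                    slot = integer(),
                                    time = as.POSIXct(character(), tz = "UTC")),
               seq_len = seq_len, horizon = horizon_slots, scaler = NULL)
    class(ws) <- "window_set"
    return(ws)
  }
  inputs <- do.call(abind_first, lapply(pieces, `[[`, "X"))
  ws <- list(inputs = inputs,
             labels = unlist(lapply(pieces, `[[`, "labels"), use.names = FALSE),
             x_T = unlist(lapply(pieces, `[[`, "x_T"), use.names = FALSE),
             anchors = do.call(rbind, lapply(pieces, `[[`, "anchors")),
             seq_len = seq_len, horizon = horizon_slots, scaler = NULL)
  class(ws) <- "window_set"
  ws
}

# rbind for 3-d arrays along the first margin (avoids an abind dependency).
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  ns <- vapply(parts, function(p) dim(p)[1], integer(1))
  out <- array(0, dim = c(sum(ns), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    if (n) out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows of %d steps x 4 channels [G, I, M, T], horizon %d slots (%d min)\n",
              n_windows(x), x$seq_len, x$horizon, x$horizon * SLOT_MIN))
  if (n_windows(x))
    cat(sprintf("  labels (dBG, mg/dL): mean %.2f, sd %.2f, range [%.1f, %.1f]\n",
                mean(x$labels), stats::sd(x$labels), min(x$labels), max(x$labels)))
  cat(if (is.null(x$scaler)) "  unscaled\n" else "  scaled (G/I/M standardized)\n")
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$inputs)[1]

#' Subset a window set by window index
#' @param ws A `window_set`.
#' @param idx Integer indices of windows to keep.
#' @return A `window_set` with the selected windows (scaler carried over).
#' @export
subset_windows <- function(ws, idx) {
  ws$inputs <- ws$inputs[idx, , , drop = FALSE]
  ws$labels <- ws$labels[idx]
  ws$x_T <- ws$x_T[idx]
  ws$anchors <- ws$anchors[idx, , drop = FALSE]
  ws
}

#' Fit / apply the per-channel affine scaler
#'
#' `fit_scaler()` computes training-set means and SDs of the glucose, insulin
#' and meal channels (over all window entries); the time-index channel is
#' already in `[0, 1)` and passes through unscaled, and labels stay in mg/dL.
#' A zero-variance channel gets scale 1 (mean shift only). `apply_scaler()`
#' standardizes a window set with a previously fitted scaler;
#' `unscale_inputs()` inverts it exactly.
#'
#' @param train A `window_set` of training windows.
#' @return `fit_scaler`: a `window_scaler` (named `center`/`scale` per
#'   channel).
#' @export
fit_scaler <- function(train) {
  if (!inherits(train, "window_set")) stopf("`train` must be a window_set")
  if (!n_windows(train)) stopf("cannot fit a scaler on an empty window_set")
  center <- numeric(4); scale <- rep(1, 4)
  for (c in 1:3) {
    v <- as.numeric(train$inputs[, , c])
    center[c] <- mean(v)
    s <- stats::sd(v)
    scale[c] <- if (is.finite(s) && s > 0) s else 1
  }
  structure(list(center = center, scale = scale,
                 channels = c("G", "I", "M", "T")),
            class = "window_scaler")
}

#' @rdname fit_scaler
#' @param ws A `window_set` to (un)scale.
#' @param scaler A `window_scaler` from `fit_scaler()`.
#' @export
apply_scaler <- function(ws, scaler) {
  if (!inherits(scaler, "window_scaler")) stopf("`scaler` must come from fit_scaler()")
  for (c in 1:4)
    ws$inputs[, , c] <- (ws$inputs[, , c] - scaler$center[c]) / scaler$scale[c]
  ws$scaler <- scaler
  ws
}

#' @rdname fit_scaler
#' @export
unscale_inputs <- function(ws, scaler = ws$scaler) {
  if (is.null(scaler)) stopf("window_set carries no scaler")
  for (c in 1:4)
    ws$inputs[, , c] <- ws$inputs[, , c] * scaler$scale[c] + scaler$center[c]
  ws$scaler <- NULL
  ws
}

#' Chronological train / validation split
#'
#' Splits windows without shuffling: the last `ceiling(val_frac * n)` windows
#' (the most recent data) form the validation set, mirroring a 90/10
#' train-validation partition of the training period.
#'
#' @param ws A `window_set` in chronological order.
#' @param val_frac Validation fraction in (0, 1); default 0.1.
#' @return `list(train =, val =)` of `window_set`s.
#' @export
split_train_val <- function(ws, val_frac = 0.1) {
  if (!is.numeric(val_frac) || val_frac <= 0 || val_frac >= 1)
    stopf("`val_frac` must be in (0, 1)")
  n <- n_windows(ws)
  nv <- ceiling(val_frac * n)
  list(train = subset_windows(ws, seq_len(n - nv)),
       val = subset_windows(ws, if (nv) (n - nv + 1L):n else integer(0)))
}

#' Seeded mini-batch index partition for one epoch
#'
#' Shuffles window indices reproducibly for a given `(seed, epoch)` and
#' partitions them into batches; the final short batch is kept.
#'
#' @param n Number of windows (or a `window_set`).
#' @param batch_size Batch size (default 512).
#' @param seed Integer seed.
#' @param epoch Epoch number (1-based); each epoch gets its own order.
#' @param shuffle Set `FALSE` for sequential batches.
#' @return List of integer index vectors, one per batch.
#' @export
make_batches <- function(n, batch_size = 512L, seed = 1L, epoch = 1L,
                         shuffle = TRUE) {
  if (inherits(n, "window_set")) n <- n_windows(n)
  if (!is_count(batch_size)) stopf("`batch_size` must be a positive integer")
  if (n == 0L) return(list())
  idx <- if (shuffle)
    with_seed(seed * 10000 + epoch, sample.int(n)) else seq_len(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Serialize a window set to disk
#'
#' Writes the input tensor flattened to CSV (one row per window,
#' `step x channel` columns) plus a JSON sidecar holding labels, current
#' glucose, anchors, shape and scaler, so a set can be rebuilt exactly.
#'
#' @param ws A `window_set`.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return Base path, invisibly.
#' @export
write_windows <- function(ws, path) {
  n <- n_windows(ws)
  flat <- matrix(ws$inputs, nrow = n)
  utils::write.csv(flat, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(seq_len = ws$seq_len, horizon = ws$horizon,
               labels = ws$labels, x_T = ws$x_T,
               anchors = list(subject_id = ws$anchors$subject_id,
                              slot = ws$anchors$slot,
                              time = format(ws$anchors$time,
                                            "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
               scaler = if (is.null(ws$scaler)) NULL else
                 list(center = ws$scaler$center, scale = ws$scaler$scale))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = I(17),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  n <- nrow(flat)
  ws <- list(
    inputs = array(as.numeric(flat), dim = c(n, meta$seq_len, 4L)),
    labels = as.numeric(meta$labels), x_T = as.numeric(meta$x_T),
    anchors = data.frame(
      subject_id = meta$anchors$subject_id, slot = meta$anchors$slot,
      time = as.POSIXct(meta$anchors$time, format = "%Y-%m-%dT%H:%M:%SZ",
                        tz = "UTC")),
    seq_len = meta$seq_len, horizon = meta$horizon,
    scaler = if (is.null(meta$scaler)) NULL else
      structure(list(center = meta$scaler$center, scale = meta$scaler$scale,
                     channels = c("G", "I", "M", "T")),
                class = "window_scaler"))
  class(ws) <- "window_set"
  ws
}
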