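# Shared fixtures and independent oracles used across the suite.

t0_utc <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

# A small hand-built series with arbitrary but valid values.
make_series <- function(n = 288, glucose = NULL, bolus = NULL, meal = NULL,
                        valid = NULL, id = "tst") {
  if (is.null(glucose)) glucose <- 120 + 10 * sin(seq_len(n) / 10)
  subject_series(id, t0_utc + 300 * (seq_len(n) - 1), glucose,
                 bolus %||% numeric(n), meal %||% numeric(n),
                 valid %||% rep(TRUE, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent stacked-RNN oracle: a plain per-timestep double loop with no
# dilation logic, valid reference for dilations all equal to 1.
stacked_rnn_oracle <- function(model, window) {
  T_len <- nrow(window)
  n <- model$hidden_size
  inp <- window
  for (l in seq_along(model$layers)) {
    cell <- model$layers[[l]]
    H <- matrix(0, T_len, n)
    h <- numeric(n)
    for (t in seq_len(T_len)) {
      h <- as.numeric(tanh(cell$W_rec %*% h + cell$W_in %*% inp[t, ] + cell$b))
      H[t, ] <- h
    }
    inp <- H
  }
  inp[T_len, ]
}

# Generic dilated oracle written independently (single window, explicit
# state bookkeeping per layer) for cross-checking dilated_forward.
dilated_oracle <- function(model, window) {
  T_len <- nrow(window)
  n <- model$hidden_size
  inp <- window
  for (l in seq_along(model$layers)) {
    d <- model$dilations[l]
    cell <- model$layers[[l]]
    H <- matrix(0, T_len, n)
    for (t in seq_len(T_len)) {
      h_prev <- if (t > d) H[t - d, ] else numeric(n)
      H[t, ] <- as.numeric(tanh(cell$W_rec %*% h_prev +
                                  cell$W_in %*% inp[t, ] + cell$b))
    }
    inp <- H
  }
  inp[T_len, ]
}

# Central finite-difference gradient of the batch loss.
numeric_gradient <- function(model, X, y, eps = 1e-5) {
  theta <- glucodrnn:::model_flatten(model)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- theta[i] + eps
    lp <- glucodrnn:::drnn_grad(glucodrnn:::model_unflatten(model, tp), X, y)$loss
    tp[i] <- theta[i] - eps
    lm <- glucodrnn:::drnn_grad(glucodrnn:::model_unflatten(model, tp), X, y)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
}

# A window_set built directly from raw arrays (bypasses make_windows) for
# unit tests that need exact control over inputs/labels.
manual_window_set <- function(X, labels, x_T = NULL) {
  n <- dim(X)[1]
  ws <- list(inputs = X, labels = labels,
             x_T = x_T %||% rep(100, n),
             anchors = data.frame(subject_id = rep("man", n), slot = seq_len(n),
                                  time = t0_utc + 300 * seq_len(n)),
             seq_len = dim(X)[2], horizon = 6L, scaler = NULL)
  class(ws) <- "window_set"
  ws
}
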