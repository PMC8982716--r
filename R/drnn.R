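#' Construct a dilated vanilla-RNN forecast model
#'
#' Builds the multi-layer dilated recurrent network: a stack of vanilla tanh
#' cells whose recurrent edge in layer `l` skips `dilations[l] - 1` timesteps
#' (`h_t^l` recurs from `h_{t - d_l}^l`), while the feed-forward edge takes
#' the layer below's output at the same timestep. An affine head (no
#' activation) maps the top layer's final state to the forecast glucose
#' change (ΔBG, mg/dL), which is added to the current reading to give the
#' forecast.
#'
#' @param input_size Channels per timestep (default 4: G, I, M, T).
#' @param hidden_size Hidden nodes per layer (default 32).
#' @param dilations Integer dilation per layer, strictly increasing powers of
#'   2 by convention (default `c(1, 2, 4)`); `c(1, 1, 1)` recovers a plain
#'   stacked RNN.
#' @param seed Seed for weight initialization.
#' @return A `drnn_model`: per-layer cells (`W_rec` `n x n`, `W_in`
#'   `n x m_l`, `b` length `n`) and head (`W` `1 x n`, `b` scalar).
#' @details Weights are drawn uniformly on `±1/sqrt(fan-in)` (fan-in = the
#'   width the matrix multiplies), biases start at zero, and all pre-window
#'   states (`t - d_l < 1`) are defined as zero vectors.
#' @examples
#' m <- drnn_model(seed = 1)
#' m
#' @export
drnn_model <- function(input_size = 4L, hidden_size = 32L,
                       dilations = c(1L, 2L, 4L), seed = 1L) {
  if (!is_count(input_size) || !is_count(hidden_size))
    stopf("`input_size` and `hidden_size` must be positive integers")
  if (!length(dilations) || any(dilations < 1) ||
      any(dilations != floor(dilations)))
    stopf("`dilations` must be positive integers")
  n <- as.integer(hidden_size)
  with_seed(seed, {
    layers <- lapply(seq_along(dilations), function(l) {
      m_l <- if (l == 1L) as.integer(input_size) else n
      list(
        W_rec = matrix(stats::runif(n * n, -1, 1) / sqrt(n), n, n),
        W_in = matrix(stats::runif(n * m_l, -1, 1) / sqrt(m_l), n, m_l),
        b = numeric(n))
    })
    head <- list(W = matrix(stats::runif(n, -1, 1) / sqrt(n), 1L, n), b = 0)
    structure(list(layers = layers, head = head,
                   dilations = as.integer(dilations),
                   hidden_size = n, input_size = as.integer(input_size)),
              class = "drnn_model")
  })
}

#' @export
print.drnn_model <- function(x, ...) {
  cat(sprintf("drnn_model: %d layers (vanilla tanh), dilations [%s], %d hidden nodes, %d input channels\n",
              length(x$layers), paste(x$dilations, collapse = ", "),
              x$hidden_size, x$input_size))
  cat(sprintf("  trainable parameters: %d (incl. %d in the forecast head)\n",
              model_param_count(x), x$hidden_size + 1L))
  invisible(x)
}

#' One vanilla RNN cell step
#'
#' `h_t = tanh(W_rec h_prev + W_in x_t + b)`. The single-gate tanh recurrence
#' used by every layer of the dilated network; `h_prev` is the layer's own
#' state one dilation back.
#'
#' @param cell List with `W_rec` (`n x n`), `W_in` (`n x m`), `b` (length
#'   `n`).
#' @param h_prev Previous hidden state, length `n` (zeros before the window).
#' @param x_t Input vector, length `m`.
#' @return Hidden state of length `n`, elementwise in `(-1, 1)`.
#' @export
vanilla_step <- function(cell, h_prev, x_t) {
  n <- nrow(cell$W_rec)
  if (length(h_prev) != n || ncol(cell$W_rec) != n)
    stopf("hidden-state size mismatch: cell is %d-dim, h_prev has length %d",
          n, length(h_prev))
  if (length(x_t) != ncol(cell$W_in))
    stopf("input size mismatch: cell expects %d, x_t has length %d",
          ncol(cell$W_in), length(x_t))
  as.numeric(tanh(cell$W_rec %*% h_prev + cell$W_in %*% x_t + cell$b))
}

#' Dilated multi-layer forward pass (single window)
#'
#' Runs the full stack over a `T x m` window. Layer `l` at timestep `t`
#' recurs from its own state at `t - d_l` (a zero vector when `t - d_l < 1`)
#' and consumes the layer-`(l-1)` output at `t` (the raw input for layer 1).
#' Returns the top layer's final state, the many-to-one summary the forecast
#' head consumes.
#'
#' @param model A [drnn_model()].
#' @param window Numeric matrix `T x input_size`, timesteps in rows.
#' @return Hidden state `h_T^L`, length `hidden_size`.
#' @export
dilated_forward <- function(model, window) {
  window <- as.matrix(window)
  T_len <- nrow(window)
  if (T_len < 1L) stopf("window must contain at least one timestep")
  if (ncol(window) != model$input_size)
    stopf("window has %d channels, model expects %d",
          ncol(window), model$input_size)
  H <- drnn_forward_batch(model, array(window, c(1L, T_len, ncol(window))))
  as.numeric(H$hidden[[length(model$layers)]][[T_len]])
}

# Batched forward pass. X is [B x T x m]. Returns hidden[[l]][[t]] = [B x n]
# matrices for every layer and timestep (kept for backpropagation).
drnn_forward_batch <- function(model, X) {
  B <- dim(X)[1]; T_len <- dim(X)[2]
  n <- model$hidden_size
  L <- length(model$layers)
  hidden <- vector("list", L)
  m <- dim(X)[3]
  inp <- lapply(seq_len(T_len), function(t) matrix(X[, t, ], B, m))
  for (l in seq_len(L)) {
    d <- model$dilations[l]
    cell <- model$layers[[l]]
    tW_rec <- t(cell$W_rec); tW_in <- t(cell$W_in)
    Hl <- vector("list", T_len)
    zero <- matrix(0, B, n)
    for (t in seq_len(T_len)) {
      h_prev <- if (t - d >= 1L) Hl[[t - d]] else zero
      A <- h_prev %*% tW_rec + inp[[t]] %*% tW_in
      Hl[[t]] <- tanh(sweep(A, 2L, cell$b, `+`))
    }
    hidden[[l]] <- Hl
    inp <- Hl
  }
  list(hidden = hidden, T_len = T_len, B = B)
}

#' Forecast head
#'
#' `y_hat = (W h + b) + x_T`: the affine head (no activation) estimates the
#' glucose change over the horizon and adds it to the current, unnormalized
#' glucose reading.
#'
#' @param model A [drnn_model()].
#' @param h Top-layer final state from [dilated_forward()] (or a `B x n`
#'   matrix of them).
#' @param x_T Current glucose, mg/dL (scalar or length-`B`).
#' @return Forecast glucose `y_hat`, mg/dL.
#' @export
drnn_predict_head <- function(model, h, x_T) {
  if (is.null(dim(h))) h <- matrix(h, 1L)
  as.numeric(h %*% t(model$head$W)) + model$head$b + x_T
}

#' Forecast a whole window set
#'
#' @param model A [drnn_model()].
#' @param ws A scaled `window_set` (inputs standardized with the training
#'   scaler; `x_T` stays raw mg/dL).
#' @return Numeric vector of glucose forecasts, mg/dL.
#' @export
predict_windows <- function(model, ws) {
  if (!n_windows(ws)) return(numeric(0))
  fw <- drnn_forward_batch(model, ws$inputs)
  h_T <- fw$hidden[[length(model$layers)]][[ws$seq_len]]
  drnn_predict_head(model, h_T, ws$x_T)
}

#' Per-state parameter-count formulas for RNN cell types
#'
#' For a cell with `n` hidden nodes and `m`-dimensional input: vanilla
#' `n^2 + m n + n`; LSTM four gates, `4 (n^2 + m n + n)`; GRU three,
#' `3 (n^2 + m n + n)`.
#'
#' @param cell_type One of `"vanilla"`, `"lstm"`, `"gru"`.
#' @param n Hidden size.
#' @param m Input size.
#' @return Integer parameter count per state.
#' @export
drnn_param_count <- function(cell_type = c("vanilla", "lstm", "gru"), n, m) {
  cell_type <- match.arg(cell_type)
  if (!is_count(n) || !is_count(m)) stopf("`n` and `m` must be >= 1")
  base <- n^2 + m * n + n
  switch(cell_type, vanilla = base, lstm = 4 * base, gru = 3 * base)
}

#' Total trainable parameters of a model
#' @param model A [drnn_model()].
#' @return Integer count over all layer matrices, biases and the head.
#' @export
model_param_count <- function(model) {
  sum(vapply(model$layers, function(l)
    length(l$W_rec) + length(l$W_in) + length(l$b), numeric(1))) +
    length(model$head$W) + 1L
}

# Flatten / restore all trainable arrays (used by the optimizer loop and
# gradient checks). Dispatches over the two trainable model classes.
model_flatten <- function(model) {
  if (inherits(model, "nnpg_model"))
    return(unlist(lapply(model$layers, function(l) list(l$W, l$b)),
                  use.names = FALSE))
  unlist(c(lapply(model$layers, function(l) list(l$W_rec, l$W_in, l$b)),
           list(model$head$W, model$head$b)), use.names = FALSE)
}

model_unflatten <- function(model, theta) {
  at <- 0L
  if (inherits(model, "nnpg_model")) {
    take <- function(k) {
      v <- theta[(at + 1L):(at + k)]
      at <<- at + k
      v
    }
    for (i in seq_along(model$layers)) {
      li <- model$layers[[i]]
      model$layers[[i]]$W <- matrix(take(length(li$W)), nrow(li$W))
      model$layers[[i]]$b <- take(length(li$b))
    }
    return(model)
  }
  take <- function(k) {
    v <- theta[(at + 1L):(at + k)]
    at <<- at + k
    v
  }
  for (l in seq_along(model$layers)) {
    cl <- model$layers[[l]]
    model$layers[[l]]$W_rec <- matrix(take(length(cl$W_rec)), nrow(cl$W_rec))
    model$layers[[l]]$W_in <- matrix(take(length(cl$W_in)), nrow(cl$W_in))
    model$layers[[l]]$b <- take(length(cl$b))
  }
  model$head$W <- matrix(take(length(model$head$W)), 1L)
  model$head$b <- take(1L)
  model
}

#' Save / load a model checkpoint
#'
#' Checkpoints are a single JSON document holding every weight array at full
#' double precision plus a manifest (dilations, sizes, optional scaler and
#' training configuration); the round trip is exact.
#'
#' @param model A [drnn_model()].
#' @param path JSON file path.
#' @param scaler Optional `window_scaler` to store alongside.
#' @param config Optional training configuration list to store.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns `list(model, scaler, config)`.
#' @export
save_checkpoint <- function(model, path, scaler = NULL, config = NULL) {
  payload <- list(
    manifest = list(
      class = "drnn_model", dilations = model$dilations,
      hidden_size = model$hidden_size, input_size = model$input_size,
      n_layers = length(model$layers),
      scaler = if (is.null(scaler)) NULL else
        list(center = scaler$center, scale = scaler$scale),
      config = config),
    layers = lapply(model$layers, function(l)
      list(W_rec = as.numeric(l$W_rec), W_in = as.numeric(l$W_in),
           b = l$b, n_in = ncol(l$W_in))),
    head = list(W = as.numeric(model$head$W), b = model$head$b))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- p$manifest$hidden_size
  layers <- lapply(seq_len(p$manifest$n_layers), function(l) {
    raw <- if (is.data.frame(p$layers)) lapply(p$layers, `[[`, l) else p$layers[[l]]
    list(W_rec = matrix(as.numeric(raw$W_rec), n, n),
         W_in = matrix(as.numeric(raw$W_in), n, raw$n_in),
         b = as.numeric(raw$b))
  })
  model <- structure(
    list(layers = layers,
         head = list(W = matrix(as.numeric(p$head$W), 1L, n),
                     b = as.numeric(p$head$b)),
         dilations = as.integer(p$manifest$dilations),
         hidden_size = as.integer(n),
         input_size = as.integer(p$manifest$input_size)),
    class = "drnn_model")
  scaler <- if (!is.null(p$manifest$scaler))
    structure(list(center = as.numeric(p$manifest$scaler$center),
                   scale = as.numeric(p$manifest$scaler$scale),
                   channels = c("G", "I", "M", "T")),
              class = "window_scaler") else NULL
  list(model = model, scaler = scaler, config = p$manifest$config)
}
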