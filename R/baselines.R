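# Classical comparison forecasters. All three consume the same window_set as
# the dilated RNN and regress the glucose change over the horizon, so metric
# differences on a shared test set isolate the predictor.

# Lagged regressor matrix: the last `order` timesteps of every channel.
arx_design <- function(ws, order) {
  T_len <- ws$seq_len
  if (order > T_len) stopf("ARX order %d exceeds the window length %d",
                           order, T_len)
  n <- n_windows(ws)
  C <- dim(ws$inputs)[3]
  Z <- matrix(0, n, order * C)
  k <- 0L
  for (c in seq_len(C)) for (j in seq_len(order)) {
    k <- k + 1L
    Z[, k] <- ws$inputs[, T_len - order + j, c]
  }
  Z
}

#' ARX baseline: lagged least squares over all channels
#'
#' Autoregressive model with exogenous inputs, order 3: the glucose change
#' over the horizon is regressed on the last `order` lags of each input
#' channel (glucose, insulin, meal, time index) plus an intercept, by
#' ordinary least squares. A rank-deficient design is solved by minimum-norm
#' least squares (SVD pseudo-inverse) and flagged.
#'
#' @param ws Training `window_set` (conventionally unscaled; any consistent
#'   scaling works as long as prediction uses the same one).
#' @param order Number of lags per channel (default 3).
#' @return An `arx_model` with `coefficients` (intercept first), `order`,
#'   and `rank_deficient` flag.
#' @export
arx_fit <- function(ws, order = 3L) {
  if (!is_count(order)) stopf("`order` must be a positive integer")
  Z <- cbind(1, arx_design(ws, order))
  p <- ncol(Z)
  if (n_windows(ws) < p)
    stopf("ARX needs at least %d training windows, got %d", p, n_windows(ws))
  fit <- stats::lm.fit(Z, ws$labels)
  rank_deficient <- fit$rank < p
  if (rank_deficient) {  # minimum-norm solution via the pseudo-inverse
    sv <- svd(Z)
    pos <- sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], ws$labels)) / sv$d[pos])
    beta <- as.numeric(beta)
  } else beta <- fit$coefficients
  structure(list(coefficients = beta, order = as.integer(order),
                 rank_deficient = rank_deficient),
            class = "arx_model")
}

#' @rdname arx_fit
#' @param fit An `arx_model`.
#' @return `arx_predict`: glucose forecasts `x_T + dBG_hat`, mg/dL.
#' @export
arx_predict <- function(fit, ws) {
  if (!inherits(fit, "arx_model")) stopf("`fit` must come from arx_fit()")
  Z <- cbind(1, arx_design(ws, fit$order))
  as.numeric(Z %*% fit$coefficients) + ws$x_T
}

#' Feed-forward baseline (three fully connected layers)
#'
#' A conventional neural network for glucose prediction: the flattened
#' window (`seq_len x 4` features) passes through two tanh hidden layers and
#' a linear output regressing the glucose change, trained with the same
#' RMSprop/mini-batch machinery as the dilated RNN (learning rate 0.001,
#' batch size 32 by default). The output layer starts at zero, so the
#' untrained network is exactly the persistence forecast.
#'
#' @param train_ws,val_ws Scaled `window_set`s.
#' @param hidden Widths of the two hidden layers.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs,patience Early-stopping budget on validation RMSE.
#' @param seed Seed for weight init and shuffling.
#' @param verbose Print per-epoch progress.
#' @return `list(model, history, best_epoch)`; the model is an `nnpg_model`.
#' @export
nnpg_train <- function(train_ws, val_ws, hidden = c(64L, 32L), lr = 0.001,
                       batch_size = 32L, max_epochs = 100L, patience = 10L,
                       seed = 1L, verbose = FALSE) {
  model <- nnpg_init(dim(train_ws$inputs)[2] * dim(train_ws$inputs)[3],
                     hidden, seed)
  config <- train_config(learning_rate = lr, batch_size = batch_size,
                         max_epochs = max_epochs, patience = patience,
                         seed = seed)
  res <- run_sgd(model, train_ws, val_ws, config,
                 grad_fun = nnpg_grad, loss_fun = NULL,
                 predict_delta = function(mod, ws)
                   nnpg_forward(mod, flatten_ws(ws))$out,
                 verbose = verbose)
  res
}

flatten_ws <- function(ws) matrix(ws$inputs, nrow = n_windows(ws))

nnpg_init <- function(n_in, hidden, seed) {
  with_seed(seed, {
    sizes <- c(n_in, hidden, 1L)
    layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
      fan_in <- sizes[i]
      W <- if (i == length(sizes) - 1L) matrix(0, sizes[i + 1L], fan_in)
      else matrix(stats::runif(sizes[i + 1L] * fan_in, -1, 1) / sqrt(fan_in),
                  sizes[i + 1L], fan_in)
      list(W = W, b = numeric(sizes[i + 1L]))
    })
    structure(list(layers = layers, sizes = sizes), class = "nnpg_model")
  })
}

nnpg_forward <- function(model, Xf) {
  A <- Xf
  acts <- list(A)
  L <- length(model$layers)
  for (i in seq_len(L)) {
    Z <- A %*% t(model$layers[[i]]$W)
    Z <- sweep(Z, 2L, model$layers[[i]]$b, `+`)
    A <- if (i < L) tanh(Z) else Z
    acts[[i + 1L]] <- A
  }
  list(out = as.numeric(A), acts = acts)
}

nnpg_grad <- function(model, X, y) {
  B <- dim(X)[1]
  Xf <- matrix(X, nrow = B)
  fw <- nnpg_forward(model, Xf)
  resid <- fw$out - y
  loss <- mean(resid^2)
  L <- length(model$layers)
  dA <- matrix(2 * resid / B, ncol = 1L)
  grads <- vector("list", L)
  for (i in L:1) {
    Z_is_linear <- i == L
    dZ <- if (Z_is_linear) dA else dA * (1 - fw$acts[[i + 1L]]^2)
    grads[[i]] <- list(W = crossprod(dZ, fw$acts[[i]]), b = colSums(dZ))
    if (i > 1L) dA <- dZ %*% model$layers[[i]]$W
  }
  list(loss = loss, grads = list(layers = grads))
}

#' @rdname nnpg_train
#' @param model An `nnpg_model`.
#' @param ws A scaled `window_set`.
#' @return `nnpg_predict`: glucose forecasts, mg/dL.
#' @export
nnpg_predict <- function(model, ws) {
  if (!inherits(model, "nnpg_model")) stopf("`model` must come from nnpg_train()")
  nnpg_forward(model, flatten_ws(ws))$out + ws$x_T
}

#' Support vector regression baseline
#'
#' Epsilon-insensitive support vector regression with an RBF kernel
#' (`C = 100`, `gamma = 0.01`) on the flattened window features, fitted with
#' the established libsvm solver in \pkg{e1071}. Targets are the glucose
#' changes standardized by the training SD (epsilon 0.1 on that scale);
#' predictions are de-standardized and added to the current glucose.
#'
#' @param train_ws Scaled training `window_set`.
#' @param C Penalty term.
#' @param gamma RBF kernel coefficient.
#' @param epsilon Tube half-width on standardized targets.
#' @param max_train Optional cap on the number of training windows (most
#'   recent kept) to bound the quadratic solver; `Inf` keeps all.
#' @return An `svr_model`.
#' @export
svr_train <- function(train_ws, C = 100, gamma = 0.01, epsilon = 0.1,
                      max_train = Inf) {
  n <- n_windows(train_ws)
  if (!n) stopf("empty training window_set")
  if (is.finite(max_train) && n > max_train)
    train_ws <- subset_windows(train_ws, (n - max_train + 1L):n)
  Xf <- flatten_ws(train_ws)
  y <- train_ws$labels
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  fit <- e1071::svm(Xf, y / y_scale, type = "eps-regression",
                    kernel = "radial", cost = C, gamma = gamma,
                    epsilon = epsilon, scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, y_scale = y_scale), class = "svr_model")
}

#' @rdname svr_train
#' @param model An `svr_model`.
#' @param ws A scaled `window_set`.
#' @return `svr_predict`: glucose forecasts, mg/dL.
#' @export
svr_predict <- function(model, ws) {
  if (!inherits(model, "svr_model")) stopf("`model` must come from svr_train()")
  # libsvm with zero support vectors (all residuals inside the tube) cannot
  # be queried through predict(); its decision function is the constant -rho
  raw <- if (model$fit$tot.nSV == 0) rep(-model$fit$rho, n_windows(ws))
  else as.numeric(stats::predict(model$fit, flatten_ws(ws)))
  raw * model$y_scale + ws$x_T
}
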