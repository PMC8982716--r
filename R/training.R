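#' Training configuration
#'
#' Hyperparameters for mini-batch RMSprop training of the dilated RNN (and
#' the feed-forward baseline, which shares the optimizer). Defaults follow
#' the tuned forecasting setup: learning rate 0.001, RMSprop decay 0.9,
#' batch size 512.
#'
#' @param learning_rate RMSprop learning rate (> 0).
#' @param rmsprop_decay Accumulator decay rho in (0, 1).
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience on validation RMSE, epochs.
#' @param grad_clip_norm Global gradient-norm clip (positive).
#' @param seed Seed controlling batch shuffling (weight init is seeded in
#'   [drnn_model()]).
#' @param phase2_epochs Fine-tuning epoch budget for [transfer_train()].
#' @param shuffle Shuffle windows between epochs (default `TRUE`).
#' @param epsilon RMSprop denominator epsilon.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, rmsprop_decay = 0.9,
                         batch_size = 512L, max_epochs = 200L,
                         patience = 10L, grad_clip_norm = 5,
                         seed = 1L, phase2_epochs = 50L, shuffle = TRUE,
                         epsilon = 1e-8) {
  if (learning_rate <= 0) stopf("`learning_rate` must be > 0")
  if (rmsprop_decay <= 0 || rmsprop_decay >= 1)
    stopf("`rmsprop_decay` must be in (0, 1)")
  if (!is_count(batch_size) || !is_count(max_epochs) || !is_count(patience))
    stopf("`batch_size`, `max_epochs`, `patience` must be positive integers")
  if (grad_clip_norm <= 0) stopf("`grad_clip_norm` must be > 0")
  if (!is_count(phase2_epochs, min = 0L)) stopf("`phase2_epochs` must be >= 0")
  structure(list(learning_rate = learning_rate, rmsprop_decay = rmsprop_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 grad_clip_norm = grad_clip_norm, seed = as.integer(seed),
                 phase2_epochs = as.integer(phase2_epochs),
                 shuffle = isTRUE(shuffle), epsilon = epsilon),
            class = "train_config")
}

#' Mini-batch training loss
#'
#' Mean squared error on the glucose-change target:
#' `mean((dBG_hat - label)^2)` in (mg/dL)^2. Since the forecast is
#' `x_T + dBG_hat`, this equals the squared forecast error.
#'
#' @param model A [drnn_model()].
#' @param ws A scaled `window_set` (the batch).
#' @return Scalar loss.
#' @export
drnn_loss <- function(model, ws) {
  if (!n_windows(ws)) stopf("loss of an empty batch is undefined")
  fw <- drnn_forward_batch(model, ws$inputs)
  h_T <- fw$hidden[[length(model$layers)]][[ws$seq_len]]
  delta <- as.numeric(h_T %*% t(model$head$W)) + model$head$b
  mean((delta - ws$labels)^2)
}

# Loss and analytic gradients for one batch, by backpropagation through time.
# X: [B x T x m], y: length-B dBG labels. Returns list(loss, grads) where
# grads mirrors the model structure.
drnn_grad <- function(model, X, y) {
  B <- dim(X)[1]; T_len <- dim(X)[2]
  L <- length(model$layers)
  n <- model$hidden_size
  fw <- drnn_forward_batch(model, X)
  H <- fw$hidden
  h_T <- H[[L]][[T_len]]
  delta <- as.numeric(h_T %*% t(model$head$W)) + model$head$b
  resid <- delta - y
  loss <- mean(resid^2)
  r <- matrix(2 * resid / B, ncol = 1L)

  grads <- list(layers = lapply(model$layers, function(l)
    list(W_rec = matrix(0, n, n), W_in = matrix(0, nrow(l$W_in), ncol(l$W_in)),
         b = numeric(n))),
    head = list(W = crossprod(r, h_T), b = sum(r)))

  # dL/dh for the layer currently being processed, one [B x n] slot per t
  dH_above <- vector("list", T_len)
  for (t in seq_len(T_len)) dH_above[[t]] <- matrix(0, B, n)
  dH_above[[T_len]] <- r %*% model$head$W

  for (l in L:1) {
    d <- model$dilations[l]
    cell <- model$layers[[l]]
    inp <- if (l == 1L) {
      m <- dim(X)[3]
      lapply(seq_len(T_len), function(t) matrix(X[, t, ], B, m))
    } else H[[l - 1L]]
    dH <- dH_above
    dInp <- if (l > 1L) lapply(seq_len(T_len), function(t) matrix(0, B, n))
            else NULL
    gW_rec <- matrix(0, n, n)
    gW_in <- matrix(0, n, ncol(cell$W_in))
    gb <- numeric(n)
    for (t in T_len:1) {
      dA <- dH[[t]] * (1 - H[[l]][[t]]^2)
      if (t - d >= 1L) {
        gW_rec <- gW_rec + crossprod(dA, H[[l]][[t - d]])
        dH[[t - d]] <- dH[[t - d]] + dA %*% cell$W_rec
      }
      gW_in <- gW_in + crossprod(dA, inp[[t]])
      gb <- gb + colSums(dA)
      if (l > 1L) dInp[[t]] <- dA %*% cell$W_in
    }
    grads$layers[[l]]$W_rec <- gW_rec
    grads$layers[[l]]$W_in <- gW_in
    grads$layers[[l]]$b <- gb
    if (l > 1L) dH_above <- dInp
  }
  list(loss = loss, grads = grads)
}

# Flatten gradients in the same order as model_flatten (either model class).
grad_flatten <- function(grads) {
  if (is.null(grads$head))
    return(unlist(lapply(grads$layers, function(l) list(l$W, l$b)),
                  use.names = FALSE))
  unlist(c(lapply(grads$layers, function(l) list(l$W_rec, l$W_in, l$b)),
           list(grads$head$W, grads$head$b)), use.names = FALSE)
}

#' RMSprop accumulator update
#'
#' The textbook recurrence: `s <- rho * s + (1 - rho) * g^2`, then
#' `theta <- theta - lr * g / (sqrt(s) + eps)`. Exposed at the vector level
#' so the optimizer can be verified on scripted gradient sequences.
#'
#' @param theta Parameter vector.
#' @param g Gradient vector.
#' @param s Accumulator vector (same length; zeros initially).
#' @param lr Learning rate.
#' @param rho Decay rate.
#' @param eps Denominator epsilon.
#' @return `list(theta =, s =)` updated.
#' @export
rmsprop_step <- function(theta, g, s, lr = 0.001, rho = 0.9, eps = 1e-8) {
  s <- rho * s + (1 - rho) * g^2
  list(theta = theta - lr * g / (sqrt(s) + eps), s = s)
}

#' Train a dilated RNN on glucose-change targets
#'
#' Mini-batch RMSprop with seeded shuffling, global gradient-norm clipping
#' and early stopping on validation RMSE. The model with the best validation
#' RMSE seen at any epoch is returned, never a later, worse one.
#'
#' @param model A [drnn_model()] (initial weights).
#' @param train_ws,val_ws Scaled `window_set`s; the scaler must have been
#'   fitted on the training windows only.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return `list(model, history, best_epoch)` where `history` is a
#'   `data.frame(epoch, train_loss, val_rmse)` (loss in (mg/dL)^2, RMSE in
#'   mg/dL).
#' @export
train_drnn <- function(model, train_ws, val_ws, config = train_config(),
                       verbose = FALSE) {
  if (!inherits(config, "train_config")) stopf("`config` must be a train_config")
  if (!n_windows(train_ws)) stopf("empty training window_set")
  if (!n_windows(val_ws)) stopf("empty validation window_set")
  run_sgd(model, train_ws, val_ws, config,
          grad_fun = drnn_grad, loss_fun = drnn_loss,
          predict_delta = function(mod, ws) {
            fw <- drnn_forward_batch(mod, ws$inputs)
            h_T <- fw$hidden[[length(mod$layers)]][[ws$seq_len]]
            as.numeric(h_T %*% t(mod$head$W)) + mod$head$b
          },
          verbose = verbose)
}

# Generic seeded mini-batch RMSprop loop shared by the DRNN and the
# feed-forward baseline. grad_fun(model, X, y) -> list(loss, grads);
# predict_delta(model, ws) -> dBG estimates.
run_sgd <- function(model, train_ws, val_ws, config, grad_fun, loss_fun,
                    predict_delta, verbose = FALSE) {
  theta <- model_flatten(model)
  s <- numeric(length(theta))
  best <- list(rmse = Inf, theta = theta, epoch = 0L)
  hist_loss <- numeric(0)
  hist_rmse <- numeric(0)
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    batches <- make_batches(n_windows(train_ws), config$batch_size,
                            seed = config$seed, epoch = epoch,
                            shuffle = config$shuffle)
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      res <- grad_fun(model,
                      train_ws$inputs[idx, , , drop = FALSE],
                      train_ws$labels[idx])
      if (!is.finite(res$loss))
        stopf("non-finite training loss at epoch %d, batch %d", epoch, bi)
      g <- grad_flatten(res$grads)
      gn <- sqrt(sum(g^2))
      if (gn > config$grad_clip_norm) g <- g * (config$grad_clip_norm / gn)
      upd <- rmsprop_step(theta, g, s, lr = config$learning_rate,
                          rho = config$rmsprop_decay, eps = config$epsilon)
      theta <- upd$theta
      s <- upd$s
      model <- model_unflatten(model, theta)
      ep_loss <- ep_loss + res$loss * length(idx)
    }
    ep_loss <- ep_loss / n_windows(train_ws)
    val_rmse <- sqrt(mean((predict_delta(model, val_ws) - val_ws$labels)^2))
    hist_loss <- c(hist_loss, ep_loss)
    hist_rmse <- c(hist_rmse, val_rmse)
    if (verbose)
      message(sprintf("epoch %3d  train loss %8.3f  val RMSE %7.3f",
                      epoch, ep_loss, val_rmse))
    if (val_rmse < best$rmse - 1e-12) {
      best <- list(rmse = val_rmse, theta = theta, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model <- model_unflatten(model, best$theta)
  list(model = model,
       history = data.frame(epoch = seq_along(hist_loss),
                            train_loss = hist_loss, val_rmse = hist_rmse),
       best_epoch = best$epoch)
}

#' Two-phase transfer learning across subjects
#'
#' Phase 1 trains a generalised model on the combined corpus from
#' [build_transfer_corpus()] (all of the target plus fixed shares of the
#' donors, doubling the training length). Phase 2 fine-tunes every weight on
#' the target subject alone for at most `config$phase2_epochs` epochs with
#' the same optimizer and early stopping; with `phase2_epochs = 0` the
#' phase-1 model is returned unchanged.
#'
#' @param target Preprocessed target [subject_series()] (training period).
#' @param donors List of preprocessed donor series.
#' @param config A [train_config()].
#' @param model Initial [drnn_model()]; a fresh default model when `NULL`.
#' @param seq_len,horizon_slots Window geometry, see [make_windows()].
#' @param val_frac Chronological validation fraction within each phase.
#' @param verbose Print per-epoch progress.
#' @return `list(model, scaler, phase1, phase2)` where `phase1`/`phase2` are
#'   the per-phase results of [train_drnn()] (`phase2` is `NULL` when
#'   skipped).
#' @export
transfer_train <- function(target, donors, config = train_config(),
                           model = NULL, seq_len = 12L, horizon_slots = 6L,
                           val_frac = 0.1, verbose = FALSE) {
  corpus <- build_transfer_corpus(target, donors)
  corpus_ws <- make_windows(corpus, seq_len, horizon_slots)
  scaler <- fit_scaler(corpus_ws)
  corpus_ws <- apply_scaler(corpus_ws, scaler)
  sp1 <- split_train_val(corpus_ws, val_frac)
  if (is.null(model))
    model <- drnn_model(input_size = 4L, seed = config$seed)
  phase1 <- train_drnn(model, sp1$train, sp1$val, config, verbose = verbose)
  if (config$phase2_epochs == 0L)
    return(list(model = phase1$model, scaler = scaler, phase1 = phase1,
                phase2 = NULL))
  target_ws <- apply_scaler(make_windows(target, seq_len, horizon_slots),
                            scaler)
  sp2 <- split_train_val(target_ws, val_frac)
  cfg2 <- config
  cfg2$max_epochs <- config$phase2_epochs
  phase2 <- train_drnn(phase1$model, sp2$train, sp2$val, cfg2,
                       verbose = verbose)
  list(model = phase2$model, scaler = scaler, phase1 = phase1,
       phase2 = phase2)
}
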