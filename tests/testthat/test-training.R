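# Loss, analytic gradients, RMSprop, the training loop and its contracts.

test_that("batch loss is the mean squared dBG error", {
  model <- drnn_model(input_size = 2, hidden_size = 3, dilations = c(1, 2),
                      seed = 5)
  X <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
  # zero model predicts dBG = 0, so loss is mean(label^2)
  zm <- glucodrnn:::model_unflatten(
    model, numeric(length(glucodrnn:::model_flatten(model))))
  ws <- manual_window_set(X, labels = c(5, 5, 5))
  expect_equal(drnn_loss(zm, ws), 25)
  # hand-computed mean of squared residuals on a 3-window batch
  delta <- vapply(1:3, function(i)
    drnn_predict_head(model, dilated_forward(model, X[i, , ]), 0),
    numeric(1))
  ws2 <- manual_window_set(X, labels = c(1, -2, 0.5))
  expect_equal(drnn_loss(model, ws2),
               mean((delta - c(1, -2, 0.5))^2))
  # perfect predictions give zero loss
  ws3 <- manual_window_set(X, labels = delta)
  expect_equal(drnn_loss(model, ws3), 0)
  expect_error(drnn_loss(model, manual_window_set(X[0, , , drop = FALSE],
                                                  numeric(0))), "empty")
})

test_that("analytic gradients match central finite differences", {
  # 2-unit, 3-step dilated model
  model <- drnn_model(input_size = 2, hidden_size = 2, dilations = c(1, 2),
                      seed = 17)
  set.seed(3)
  X <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  y <- rnorm(4)
  analytic <- glucodrnn:::grad_flatten(glucodrnn:::drnn_grad(model, X, y)$grads)
  numeric <- numeric_gradient(model, X, y)
  rel <- abs(analytic - numeric) / pmax(abs(numeric), 1e-8)
  expect_lt(max(rel), 1e-4)
  # and for the default three-layer dilation stack on a 12-step window
  m2 <- drnn_model(input_size = 4, hidden_size = 3, seed = 23)
  X2 <- array(rnorm(2 * 12 * 4), c(2, 12, 4))
  y2 <- rnorm(2)
  a2 <- glucodrnn:::grad_flatten(glucodrnn:::drnn_grad(m2, X2, y2)$grads)
  n2 <- numeric_gradient(m2, X2, y2)
  expect_lt(max(abs(a2 - n2) / pmax(abs(n2), 1e-8)), 1e-4)
})

test_that("RMSprop follows the textbook accumulator recurrence", {
  theta <- c(1, -2)
  s <- c(0, 0)
  gs <- list(c(0.5, -1), c(0.2, 0.3), c(-0.4, 0.1))
  s_ref <- s
  th_ref <- theta
  for (g in gs) {
    upd <- rmsprop_step(theta, g, s, lr = 0.01, rho = 0.9, eps = 1e-8)
    s_ref <- 0.9 * s_ref + 0.1 * g^2
    th_ref <- th_ref - 0.01 * g / (sqrt(s_ref) + 1e-8)
    expect_equal(upd$s, s_ref)
    expect_equal(upd$theta, th_ref)
    theta <- upd$theta
    s <- upd$s
  }
})

test_that("training reduces the loss, is seed-reproducible, lr=0 is a no-op", {
  sc <- sim_scenario(n_days = 2, seed = 33)
  ws <- make_windows(simulate_subject(sc))
  ws <- subset_windows(ws, 1:220)
  scaler <- fit_scaler(ws)
  sp <- split_train_val(apply_scaler(ws, scaler), 0.1)
  model <- drnn_model(hidden_size = 8, seed = 2)
  cfg <- train_config(max_epochs = 5, patience = 5, batch_size = 64, seed = 9)
  fit <- train_drnn(model, sp$train, sp$val, cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # determinism: identical config and seeds give an identical history
  fit2 <- train_drnn(model, sp$train, sp$val, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(glucodrnn:::model_flatten(fit$model),
                   glucodrnn:::model_flatten(fit2$model))
  # a zero-learning-rate optimizer step leaves every weight bitwise unchanged
  th <- glucodrnn:::model_flatten(model)
  upd <- rmsprop_step(th, rnorm(length(th)), numeric(length(th)), lr = 0)
  expect_identical(upd$theta, th)
  # early stopping returns the best validation model seen
  val_rmse_returned <- sqrt(mean((
    glucodrnn:::drnn_grad(fit$model,
                          sp$val$inputs, sp$val$labels)$loss)))
  expect_lte(round(val_rmse_returned, 10),
             round(min(fit$history$val_rmse), 10))
})

test_that("non-finite loss aborts with the epoch and batch named", {
  ws <- make_windows(make_series(60))
  scaler <- fit_scaler(ws)
  sp <- split_train_val(apply_scaler(ws, scaler), 0.2)
  model <- drnn_model(hidden_size = 4, seed = 1)
  model$head$b <- Inf
  cfg <- train_config(max_epochs = 2, patience = 2, batch_size = 16, seed = 1)
  expect_error(train_drnn(model, sp$train, sp$val, cfg),
               "epoch 1, batch 1")
})

test_that("transfer learning: phase 2 with zero epochs returns phase-1 model", {
  sc <- sim_scenario(n_days = 2, seed = 51)
  target <- simulate_subject(sc, subject_id = "tgt")
  donors <- lapply(1:5, function(i) {
    sci <- sim_scenario(n_days = 1, seed = 60 + i)
    simulate_subject(sci, subject_id = paste0("don", i))
  })
  cfg <- train_config(max_epochs = 2, patience = 2, batch_size = 256,
                      seed = 4, phase2_epochs = 0L)
  tf <- transfer_train(target, donors, cfg)
  expect_null(tf$phase2)
  expect_identical(glucodrnn:::model_flatten(tf$model),
                   glucodrnn:::model_flatten(tf$phase1$model))
  # with phase-2 epochs the fine-tuned model differs and history exists
  cfg2 <- train_config(max_epochs = 2, patience = 2, batch_size = 256,
                       seed = 4, phase2_epochs = 2L)
  tf2 <- transfer_train(target, donors, cfg2)
  expect_false(identical(glucodrnn:::model_flatten(tf2$model),
                         glucodrnn:::model_flatten(tf2$phase1$model)))
  expect_equal(nrow(tf2$phase2$history), 2)
})
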