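# Window construction, channel layout, scaler, chronological split, batching.

test_that("window counting and the dBG label follow the sliding contract", {
  n <- 18
  g <- 100 + cumsum(rep(1, n))
  s <- make_series(n, glucose = g)
  ws <- make_windows(s, seq_len = 12, horizon_slots = 6)
  expect_equal(n_windows(ws), 1)       # 18 - 12 - 6 + 1
  expect_equal(ws$labels, g[18] - g[12])
  expect_equal(ws$x_T, g[12])
  # constant series labels are all zero
  ws0 <- make_windows(make_series(40, glucose = rep(120, 40)))
  expect_true(all(ws0$labels == 0))
  # shorter than seq_len + horizon: empty set, not an error
  expect_equal(n_windows(make_windows(make_series(17))), 0)
})

test_that("windows never span invalid slots and respect segment counting", {
  n <- 100
  s <- make_series(n)
  s$valid[41] <- FALSE
  ws <- make_windows(s, 12, 6)
  # segments of length 40 and 59 -> (40-17) + (59-17) windows
  expect_equal(n_windows(ws), (40 - 17) + (59 - 17))
  # no window's slots include the invalid slot: check via anchors
  bad_range <- 41 - 6  # any anchor in [35, 46] would touch slot 41
  expect_false(any(ws$anchors$slot >= 41 - 6 & ws$anchors$slot <= 41 + 5))
  # causality: every input slot precedes the label slot
  expect_true(all(ws$anchors$slot + 6 <= n))
})

test_that("channel layout is [G, I, M, T] with events kept sparse", {
  n <- 30
  s <- make_series(n, bolus = c(rep(0, 14), 2.5, rep(0, 15)),
                   meal = c(rep(0, 19), 60, rep(0, 10)))
  ws <- make_windows(s, 12, 6)
  w1 <- ws$inputs[1, , ]   # slots 1..12
  expect_equal(w1[, 1], s$glucose[1:12])
  expect_equal(w1[, 2], s$bolus[1:12])
  expect_equal(w1[, 3], s$meal[1:12])
  expect_equal(w1[, 4], time_index(s$time[1:12]))
  # the bolus appears only at its administration slot
  expect_equal(sum(ws$inputs[, , 2] > 0), sum(15 >= ws$anchors$slot - 11 &
                                                15 <= ws$anchors$slot))
})

test_that("scaler standardizes G/I/M on training stats and passes T through", {
  sc <- sim_scenario(n_days = 3, seed = 21)
  ws <- make_windows(simulate_subject(sc))
  scaler <- fit_scaler(ws)
  scaled <- apply_scaler(ws, scaler)
  for (c in 1:3) {
    v <- as.numeric(scaled$inputs[, , c])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  expect_identical(scaled$inputs[, , 4], ws$inputs[, , 4])
  expect_identical(scaled$labels, ws$labels)     # labels stay mg/dL
  # exact affine round trip
  back <- unscale_inputs(scaled, scaler)
  expect_equal(back$inputs, ws$inputs, tolerance = 1e-12)
  # zero-variance channel: scale 1, shift only
  ws0 <- make_windows(make_series(40, glucose = rep(120, 40)))
  sc0 <- fit_scaler(ws0)
  expect_equal(sc0$scale[1], 1)
  expect_equal(sc0$center[1], 120)
})

test_that("train/val split is chronological from the end", {
  ws <- make_windows(make_series(117))   # 100 windows
  expect_equal(n_windows(ws), 100)
  sp <- split_train_val(ws, 0.1)
  expect_equal(n_windows(sp$train), 90)
  expect_equal(n_windows(sp$val), 10)
  expect_true(max(sp$train$anchors$slot) < min(sp$val$anchors$slot))
  # ceiling: smallest positive fraction still yields one window
  sp2 <- split_train_val(ws, 0.001)
  expect_equal(n_windows(sp2$val), 1)
  expect_error(split_train_val(ws, 0), "val_frac")
  expect_error(split_train_val(ws, 1), "val_frac")
  # nested 90/10 after a 90/10 outer partition gives 81/9/10 overall
  n <- n_windows(ws)
  test_n <- floor(0.1 * n)
  inner <- split_train_val(subset_windows(ws, seq_len(n - test_n)), 0.1)
  expect_equal(n_windows(inner$train) / n, 0.81)
  expect_equal(n_windows(inner$val) / n, 0.09)
})

test_that("batch partition is seeded, exhaustive and keeps the short tail", {
  b <- make_batches(1030, batch_size = 512, seed = 7, epoch = 1)
  expect_equal(vapply(b, length, numeric(1)), c(512, 512, 6),
               ignore_attr = TRUE)
  expect_setequal(unlist(b), 1:1030)
  expect_identical(make_batches(1030, 512, seed = 7, epoch = 1), b)
  expect_false(identical(make_batches(1030, 512, seed = 7, epoch = 2), b))
  expect_equal(make_batches(0, 512, seed = 1), list())
  # unshuffled mode is sequential
  bs <- make_batches(10, 4, seed = 1, shuffle = FALSE)
  expect_equal(unlist(bs), 1:10, ignore_attr = TRUE)
})

test_that("window sets serialize to CSV + JSON and rebuild exactly", {
  ws <- make_windows(make_series(60))
  scaler <- fit_scaler(ws)
  ws <- apply_scaler(ws, scaler)
  base <- file.path(tempdir(), "ws-roundtrip")
  write_windows(ws, base)
  back <- read_windows(base)
  expect_equal(back$inputs, ws$inputs, tolerance = 1e-12)
  expect_equal(back$labels, ws$labels)
  expect_equal(back$x_T, ws$x_T)
  expect_equal(back$scaler$center, ws$scaler$center)
  expect_equal(back$anchors$slot, ws$anchors$slot)
})
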