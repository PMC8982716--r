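# Gap detection, interpolation, median filtering, causal extrapolation,
# time index, transfer-corpus construction.

test_that("detect_gaps run-length encodes invalid slots", {
  s <- make_series(20)
  expect_equal(nrow(detect_gaps(s)), 0)
  s$valid[c(3, 4, 9)] <- FALSE
  g <- detect_gaps(s)
  expect_equal(g$start, c(3, 9))
  expect_equal(g$length, c(2, 1))
  # a literal non-positive reading counts as invalid even when flagged valid
  s2 <- make_series(20)
  s2$glucose[5] <- NA
  s2$valid[5] <- FALSE
  expect_equal(detect_gaps(s2)$start, 5)
})

test_that("ten zero readings between 7:35 and 8:25 form one length-10 gap", {
  s <- make_series(288)
  first <- which(format(s$time, "%H:%M") == "07:40")  # strictly after 7:35
  s$valid[first:(first + 9)] <- FALSE
  g <- detect_gaps(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$length, 10)
  filled <- fill_gaps_linear(s, max_gap_slots = 24)
  expect_equal(sum(!s$valid) - sum(!filled$valid), 10)
  expect_true(all(filled$valid))
})

test_that("linear fill draws the straight line between bounding samples", {
  g <- c(100, NA, NA, NA, NA, 150, 160)
  s <- make_series(7, glucose = g, valid = !is.na(g))
  out <- fill_gaps_linear(s)
  expect_equal(out$glucose[2:5], c(110, 120, 130, 140))
  expect_true(all(out$valid))
  # idempotent, and valid samples never altered
  expect_equal(fill_gaps_linear(out)$glucose, out$glucose)
  expect_equal(out$glucose[c(1, 6, 7)], g[c(1, 6, 7)])
})

test_that("gaps above the cap and boundary gaps stay unfilled", {
  g <- c(100, rep(NA, 4), 150)
  s <- make_series(6, glucose = g, valid = !is.na(g))
  out <- fill_gaps_linear(s, max_gap_slots = 3)   # gap length 4 > cap
  expect_equal(sum(!out$valid), 4)
  # boundary gap: no left bounding sample
  g2 <- c(NA, NA, 120, 125, 130)
  s2 <- make_series(5, glucose = g2, valid = !is.na(g2))
  out2 <- fill_gaps_linear(s2)
  expect_equal(sum(!out2$valid), 2)
})

test_that("median filter removes spikes, keeps monotone series, matches brute force", {
  s <- make_series(5, glucose = c(100, 100, 400, 100, 100))
  expect_equal(median_filter_series(s, 3)$glucose, rep(100, 5))
  mono <- make_series(30, glucose = 100 + seq_len(30))
  expect_equal(median_filter_series(mono, 5)$glucose, mono$glucose)
  set.seed(11)
  x <- 120 + rnorm(101, sd = 15)
  s3 <- make_series(101, glucose = pmax(x, 1))
  out <- median_filter_series(s3, 5)$glucose
  brute <- vapply(seq_along(x), function(i) {
    k <- min(2, i - 1, length(x) - i)
    median(s3$glucose[(i - k):(i + k)])
  }, numeric(1))
  expect_equal(out, brute)
  # window-boundedness invariant at interior slots
  for (i in 3:99)
    expect_true(out[i] >= min(s3$glucose[(i - 2):(i + 2)]) &&
                  out[i] <= max(s3$glucose[(i - 2):(i + 2)]))
  expect_error(median_filter_series(s3, 4), "odd")
})

test_that("median filter does not bridge gaps and leaves other channels alone", {
  g <- c(100, 100, 300, NA, 100, 100, 100)
  s <- make_series(7, glucose = g, valid = !is.na(g),
                   bolus = rep(1, 7), meal = rep(2, 7))
  out <- median_filter_series(s, 3)
  expect_true(is.na(out$glucose[4]))
  expect_identical(out$bolus, s$bolus)
  expect_identical(out$meal, s$meal)
  # the spike at the segment edge (slot 3, neighbourless on the right)
  # shrinks its window to itself and passes through
  expect_equal(out$glucose[3], 300)
})

test_that("extrapolation continues the recent least-squares trend causally", {
  # slope continuation, k = 2 degenerate case
  expect_equal(as.numeric(extrapolate_forward(c(100, 110), 1)), 120)
  expect_equal(as.numeric(extrapolate_forward(rep(95, 10), 3)), rep(95, 3))
  # k = 6 noisy linear history matches a closed-form regression oracle
  set.seed(4)
  h <- 100 + 2 * (1:12) + rnorm(12, sd = 1)
  out <- extrapolate_forward(h, 4, k = 6)
  t_obs <- 7:12
  fit <- lm(h[t_obs] ~ t_obs)
  oracle <- unname(predict(fit, data.frame(t_obs = 13:16)))
  expect_equal(as.numeric(out), oracle, tolerance = 1e-9)
  # causal: appending future data cannot change the estimate for slot 13
  expect_equal(out[1], extrapolate_forward(h, 1, k = 6)[1])
  # single trailing sample falls back to hold-last-value, flagged
  fb <- extrapolate_forward(c(NA, 130), 2)
  expect_equal(as.numeric(fb), c(130, 130))
  expect_true(attr(fb, "fallback"))
})

test_that("time index maps the day onto [0, 1) as slot/288", {
  tms <- as.POSIXct(c("2024-03-05 00:00", "2024-03-05 12:00",
                      "2024-03-05 23:55"), tz = "UTC")
  expect_equal(time_index(tms), c(0, 0.5, 287 / 288))
  expect_error(time_index(as.POSIXct("2024-03-05 00:02", tz = "UTC")),
               "grid")
  # periodic across days, injective within a day
  s <- make_series(2 * 288)
  ti <- time_index(s$time)
  expect_equal(ti[1:288], ti[289:576])
  expect_equal(anyDuplicated(ti[1:288]), 0)
})

test_that("transfer corpus doubles the target with equal donor shares", {
  target <- make_series(1000, id = "target")
  donors <- lapply(1:5, function(i) make_series(300, id = paste0("d", i)))
  corpus <- build_transfer_corpus(target, donors)
  expect_length(corpus, 6)
  expect_identical(corpus[[1]]$glucose, target$glucose)
  lens <- vapply(corpus, function(s) s$n_slots, numeric(1))
  expect_equal(lens, c(1000, rep(200, 5)))
  expect_equal(sum(lens), 2 * 1000)
  # donor blocks are the final contiguous block of each donor
  expect_identical(corpus[[2]]$glucose, donors[[1]]$glucose[101:300])
  short <- c(donors[1:4], list(make_series(150, id = "shorty")))
  expect_error(build_transfer_corpus(target, short), "shorty")
})
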