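# End-to-end experiment drivers: per-subject benchmark of the dilated RNN
# against the classical baselines, and the YAML-driven pipeline behind the
# command-line interface.

#' Benchmark forecasters on one subject
#'
#' Splits a subject's record chronologically into a training and a test
#' period, preprocesses the training part (interpolation + median filter),
#' builds windows, fits the requested forecasters and evaluates each on the
#' identical test windows.
#'
#' @param series A [subject_series()].
#' @param train_days,test_days Length of the two periods, days (taken from
#'   the start and end of the record respectively).
#' @param methods Subset of `c("drnn", "arx", "svr", "nnpg")`.
#' @param config A [train_config()] for the neural forecasters.
#' @param donors Optional list of donor series; when given, the DRNN is
#'   trained with two-phase transfer learning instead of from scratch.
#' @param seq_len,horizon_slots Window geometry.
#' @param svr_max_train Cap on SVR training windows (see [svr_train()]).
#' @param nnpg_epochs Epoch budget for the feed-forward baseline.
#' @return `data.frame(method, subject, rmse, mard, time_lag)`, one row per
#'   method.
#' @export
benchmark_subject <- function(series, train_days, test_days,
                              methods = c("drnn", "arx", "svr", "nnpg"),
                              config = train_config(),
                              donors = NULL,
                              seq_len = 12L, horizon_slots = 6L,
                              svr_max_train = 2000L,
                              nnpg_epochs = 40L) {
  methods <- match.arg(methods, several.ok = TRUE)
  n_train <- train_days * SLOTS_PER_DAY
  n_test <- test_days * SLOTS_PER_DAY
  if (n_train + n_test > series$n_slots)
    stopf("series '%s' too short for %g + %g days", series$subject_id,
          train_days, test_days)
  train_series <- preprocess_series(slice_series(series, 1L, n_train))
  test_series <- slice_series(series, series$n_slots - n_test + 1L,
                              series$n_slots)
  train_raw <- make_windows(train_series, seq_len, horizon_slots)
  test_raw <- make_windows(test_series, seq_len, horizon_slots)
  if (!n_windows(train_raw) || !n_windows(test_raw))
    stopf("no usable windows for subject '%s'", series$subject_id)
  scaler <- fit_scaler(train_raw)
  train_ws <- apply_scaler(train_raw, scaler)
  test_ws <- apply_scaler(test_raw, scaler)
  sp <- split_train_val(train_ws, 0.1)
  actual <- test_ws$x_T + test_ws$labels

  rows <- list()
  add <- function(method, pred) {
    ev <- evaluate_forecasts(pred, actual, max_lag_slots = horizon_slots)
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(method = method, subject = series$subject_id), ev)
  }
  if ("drnn" %in% methods) {
    if (is.null(donors)) {
      model <- drnn_model(seed = config$seed)
      fit <- train_drnn(model, sp$train, sp$val, config)
      add("drnn", predict_windows(fit$model, test_ws))
    } else {
      donors_pp <- lapply(donors, function(d)
        preprocess_series(slice_series(d, 1L, min(n_train, d$n_slots))))
      tf <- transfer_train(train_series, donors_pp, config,
                           seq_len = seq_len, horizon_slots = horizon_slots)
      # transfer scaler is fitted on the corpus; rescale the test windows
      test_tf <- apply_scaler(test_raw, tf$scaler)
      add("drnn", predict_windows(tf$model, test_tf))
    }
  }
  if ("arx" %in% methods) {
    arx <- arx_fit(train_raw, order = 3L)
    add("arx", arx_predict(arx, test_raw))
  }
  if ("svr" %in% methods) {
    svr <- svr_train(train_ws, max_train = svr_max_train)
    add("svr", svr_predict(svr, test_ws))
  }
  if ("nnpg" %in% methods) {
    nn <- nnpg_train(sp$train, sp$val, max_epochs = nnpg_epochs,
                     patience = config$patience, seed = config$seed)
    add("nnpg", nnpg_predict(nn$model, test_ws))
  }
  do.call(rbind, rows)
}

#' Benchmark forecasters over a cohort
#'
#' Runs [benchmark_subject()] for every subject and collects a long metrics
#' table ready for [metrics_report()].
#'
#' @param cohort List of [subject_series()].
#' @param ... Passed to [benchmark_subject()].
#' @return Long `data.frame` of per-subject, per-method metrics.
#' @export
benchmark_cohort <- function(cohort, ...) {
  do.call(rbind, lapply(cohort, benchmark_subject, ...))
}

#' Run the full pipeline from a YAML configuration
#'
#' Executes simulate -> preprocess -> window -> train -> evaluate according
#' to a config file and writes all artifacts (per-subject CSVs, metric
#' reports, a manifest with the config hash and seed) under the configured
#' output directory. Rerunning with the same config reproduces every number
#' exactly.
#'
#' @param config_path Path to a YAML config; see the packaged example
#'   `system.file("config", "pipeline-example.yaml", package = "glucodrnn")`.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The [metrics_report()] of the benchmark, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  bad <- setdiff(names(cfg), c("scenario", "cohort", "split", "train",
                               "methods", "out_dir", "transfer"))
  if (length(bad)) stopf("unknown config sections: %s", paste(bad, collapse = ", "))
  for (sec in c("scenario", "cohort", "split"))
    if (is.null(cfg[[sec]])) stopf("config is missing the '%s' section", sec)
  if (is.null(cfg$cohort$n_subjects)) stopf("config field missing: cohort.n_subjects")
  if (is.null(cfg$split$train_days)) stopf("config field missing: split.train_days")
  if (is.null(cfg$split$test_days)) stopf("config field missing: split.test_days")
  out_dir <- out_dir %||% cfg$out_dir %||% "glucodrnn-output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ph <- default_physiology()
  if (!is.null(cfg$scenario$physiology))
    ph <- utils::modifyList(ph, cfg$scenario$physiology)
  sc_args <- cfg$scenario[setdiff(names(cfg$scenario), "physiology")]
  scenario <- do.call(sim_scenario, c(sc_args, list(physiology = ph)))
  cohort <- simulate_cohort(cfg$cohort$n_subjects, scenario,
                            physiology_cv = cfg$cohort$physiology_cv %||% 0.1)
  for (s in cohort)
    write_subject_csv(s, file.path(out_dir, paste0(s$subject_id, ".csv")))

  config <- do.call(train_config, cfg$train %||% list())
  methods <- unlist(cfg$methods) %||% c("drnn", "arx")
  use_transfer <- isTRUE(cfg$transfer)
  metrics <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    donors <- if (use_transfer) cohort[-i] else NULL
    benchmark_subject(cohort[[i]], cfg$split$train_days, cfg$split$test_days,
                      methods = methods, config = config, donors = donors)
  }))
  report <- metrics_report(metrics,
                           reference = if ("drnn" %in% methods) "drnn"
                                       else methods[1])
  write_report(report, file.path(out_dir, "report"))
  manifest <- list(config_path = normalizePath(config_path),
                   config_md5 = unname(tools::md5sum(config_path)),
                   seed = scenario$seed,
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
                   methods = methods)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(report)
}
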