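#' Simulation scenario for a synthetic CGM subject
#'
#' Bundles the generative parameters of the synthetic cohort: daily meal and
#' bolus statistics, the physiological parameters of the glucose-insulin-meal
#' minimal model, sensor-noise settings and the RNG seed.
#'
#' @param n_days Number of simulated days (>= 1).
#' @param meals_per_day Meals per day (default 3).
#' @param meal_size_mean Mean carbohydrate per meal, grams.
#' @param meal_size_cv Coefficient of variation of meal size (default 0.10).
#' @param meal_time_std Standard deviation of meal timing, minutes
#'   (default 20).
#' @param boluses_per_day_range Integer interval `c(lo, hi)` for the number of
#'   insulin boluses per day, drawn uniformly per day (default `c(1, 5)`).
#' @param bolus_dose_mean Mean bolus size, insulin units.
#' @param bolus_dose_cv Coefficient of variation of bolus size.
#' @param bolus_time_jitter_sd SD (minutes) of the jitter around the meal time
#'   a bolus is anchored to; boluses are not forced to coincide with meals.
#' @param physiology Named list of minimal-model parameters, see
#'   [default_physiology()]. All rates must be positive.
#' @param sensor_noise_sd Marginal SD of the additive AR(1) sensor noise,
#'   mg/dL.
#' @param noise_ar1 Lag-1 autocorrelation of the sensor noise (default 0.7).
#' @param seed Integer RNG seed; the same scenario always yields the same
#'   subject.
#'
#' @return An object of class `sim_scenario`.
#' @seealso [simulate_subject()]
#' @export
sim_scenario <- function(n_days,
                         meals_per_day = 3L,
                         meal_size_mean = 60,
                         meal_size_cv = 0.10,
                         meal_time_std = 20,
                         boluses_per_day_range = c(1L, 5L),
                         bolus_dose_mean = 6,
                         bolus_dose_cv = 0.20,
                         bolus_time_jitter_sd = 30,
                         physiology = default_physiology(),
                         sensor_noise_sd = 3,
                         noise_ar1 = 0.7,
                         seed = 1L) {
  if (!is_count(n_days)) stopf("`n_days` must be a positive integer")
  if (!is_count(meals_per_day, min = 0L)) stopf("`meals_per_day` must be a count")
  if (meal_size_cv < 0) stopf("`meal_size_cv` must be >= 0")
  if (meal_time_std < 0) stopf("`meal_time_std` must be >= 0")
  r <- boluses_per_day_range
  if (length(r) != 2L || any(r != floor(r)) || r[1] > r[2] ||
      r[1] < 0 || r[2] > 24)
    stopf("`boluses_per_day_range` must be an integer interval within [0, 24]")
  if (sensor_noise_sd < 0) stopf("`sensor_noise_sd` must be >= 0")
  if (noise_ar1 < 0 || noise_ar1 >= 1) stopf("`noise_ar1` must be in [0, 1)")
  check_physiology(physiology)
  structure(
    list(n_days = as.integer(n_days), meals_per_day = as.integer(meals_per_day),
         meal_size_mean = meal_size_mean, meal_size_cv = meal_size_cv,
         meal_time_std = meal_time_std,
         boluses_per_day_range = as.integer(r),
         bolus_dose_mean = bolus_dose_mean, bolus_dose_cv = bolus_dose_cv,
         bolus_time_jitter_sd = bolus_time_jitter_sd,
         physiology = physiology,
         sensor_noise_sd = sensor_noise_sd, noise_ar1 = noise_ar1,
         seed = as.integer(seed)),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_scenario: %d days, %d meals/day (%.0f g, CV %.0f%%, timing SD %.0f min),\n",
    "  %d-%d boluses/day (%.1f U), sensor noise SD %.1f mg/dL (AR1 %.2f), seed %d\n"),
    x$n_days, x$meals_per_day, x$meal_size_mean, 100 * x$meal_size_cv,
    x$meal_time_std, x$boluses_per_day_range[1], x$boluses_per_day_range[2],
    x$bolus_dose_mean, x$sensor_noise_sd, x$noise_ar1, x$seed))
  invisible(x)
}

#' Default minimal-model physiology
#'
#' Parameters of the Bergman-style minimal model used by the simulator:
#' glucose kinetics `dG/dt = -p1 (G - Gb) - X G + f kgut Q2 / Vg`, remote
#' insulin action `dX/dt = -p2 X + p3 Ip`, a two-compartment gut chain
#' (`Q1 -> Q2`, rate `kgut`) receiving meal carbohydrate, and a
#' two-compartment subcutaneous insulin chain (`S1 -> S2`, time constant
#' `tmax_i`) with plasma insulin `Ip = S2 / (tmax_i Vi)` above basal.
#'
#' @param p1 Glucose effectiveness, 1/min.
#' @param p2 Decay rate of remote insulin action, 1/min.
#' @param p3 Insulin sensitivity gain, (mU/L)^-1 min^-2.
#' @param Gb Basal glucose, mg/dL.
#' @param kgut Gut-absorption rate constant, 1/min.
#' @param Vg Glucose distribution volume, dL.
#' @param tmax_i Subcutaneous insulin absorption time constant, min.
#' @param Vi Plasma insulin distribution volume, L.
#' @param f Carbohydrate bioavailability, fraction.
#' @return Named list of positive parameters.
#' @export
default_physiology <- function(p1 = 0.02, p2 = 0.02, p3 = 4e-5, Gb = 110,
                               kgut = 1 / 40, Vg = 160, tmax_i = 55,
                               Vi = 8.4, f = 0.8) {
  list(p1 = p1, p2 = p2, p3 = p3, Gb = Gb, kgut = kgut, Vg = Vg,
       tmax_i = tmax_i, Vi = Vi, f = f)
}

check_physiology <- function(ph) {
  need <- names(default_physiology())
  miss <- setdiff(need, names(ph))
  if (length(miss)) stopf("physiology missing parameters: %s",
                          paste(miss, collapse = ", "))
  bad <- need[!vapply(ph[need], function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad)) stopf("physiology parameters must be positive finite: %s",
                         paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Integrate the minimal model with fixed-step RK4 at a 1-min internal step.
# meal_mg / bolus_mU are per-minute impulse vectors (mg carbohydrate entering
# the gut, mU insulin entering the subcutaneous depot). Returns glucose at
# every minute.
integrate_minimal_model <- function(n_min, meal_mg, bolus_mU, ph) {
  p1 <- ph$p1; p2 <- ph$p2; p3 <- ph$p3; Gb <- ph$Gb
  kg <- ph$kgut; Vg <- ph$Vg; ti <- ph$tmax_i; Vi <- ph$Vi; f <- ph$f
  G <- Gb; X <- 0; Q1 <- 0; Q2 <- 0; S1 <- 0; S2 <- 0
  out <- numeric(n_min)
  ci <- 1 / (ti * Vi)      # S2 -> plasma insulin concentration (mU/L)
  cg <- f * kg / Vg        # Q2 -> glucose appearance (mg/dL/min)
  for (t in seq_len(n_min)) {
    Q1 <- Q1 + meal_mg[t]
    S1 <- S1 + bolus_mU[t]
    # RK4 stages, derivative inlined for speed
    dG1 <- -p1 * (G - Gb) - X * G + cg * Q2
    dX1 <- -p2 * X + p3 * S2 * ci
    dQ11 <- -kg * Q1; dQ21 <- kg * (Q1 - Q2)
    dS11 <- -S1 / ti; dS21 <- (S1 - S2) / ti

    G2 <- G + 0.5 * dG1; X2 <- X + 0.5 * dX1
    Q12 <- Q1 + 0.5 * dQ11; Q22 <- Q2 + 0.5 * dQ21
    S12 <- S1 + 0.5 * dS11; S22 <- S2 + 0.5 * dS21
    dG2 <- -p1 * (G2 - Gb) - X2 * G2 + cg * Q22
    dX2 <- -p2 * X2 + p3 * S22 * ci
    dQ12 <- -kg * Q12; dQ22 <- kg * (Q12 - Q22)
    dS12 <- -S12 / ti; dS22 <- (S12 - S22) / ti

    G3 <- G + 0.5 * dG2; X3 <- X + 0.5 * dX2
    Q13 <- Q1 + 0.5 * dQ12; Q23 <- Q2 + 0.5 * dQ22
    S13 <- S1 + 0.5 * dS12; S23 <- S2 + 0.5 * dS22
    dG3 <- -p1 * (G3 - Gb) - X3 * G3 + cg * Q23
    dX3 <- -p2 * X3 + p3 * S23 * ci
    dQ13 <- -kg * Q13; dQ23 <- kg * (Q13 - Q23)
    dS13 <- -S13 / ti; dS23 <- (S13 - S23) / ti

    G4 <- G + dG3; X4 <- X + dX3
    Q14 <- Q1 + dQ13; Q24 <- Q2 + dQ23
    S14 <- S1 + dS13; S24 <- S2 + dS23
    dG4 <- -p1 * (G4 - Gb) - X4 * G4 + cg * Q24
    dX4 <- -p2 * X4 + p3 * S24 * ci
    dQ14 <- -kg * Q14; dQ24 <- kg * (Q14 - Q24)
    dS14 <- -S14 / ti; dS24 <- (S14 - S24) / ti

    G <- G + (dG1 + 2 * dG2 + 2 * dG3 + dG4) / 6
    X <- X + (dX1 + 2 * dX2 + 2 * dX3 + dX4) / 6
    Q1 <- Q1 + (dQ11 + 2 * dQ12 + 2 * dQ13 + dQ14) / 6
    Q2 <- Q2 + (dQ21 + 2 * dQ22 + 2 * dQ23 + dQ24) / 6
    S1 <- S1 + (dS11 + 2 * dS12 + 2 * dS13 + dS14) / 6
    S2 <- S2 + (dS21 + 2 * dS22 + 2 * dS23 + dS24) / 6
    out[t] <- G
  }
  out
}

# Canonical meal anchor times (minutes from midnight). Three meals fall at
# 8:00, 13:00 and 19:00; other counts are spread evenly over 07:00-20:00.
meal_anchor_minutes <- function(meals_per_day) {
  if (meals_per_day == 0L) return(numeric(0))
  if (meals_per_day == 3L) return(c(8, 13, 19) * 60)
  seq(7 * 60, 20 * 60, length.out = meals_per_day)
}

#' Simulate one synthetic CGM subject
#'
#' Draws daily meal and bolus events from the scenario statistics, integrates
#' the minimal model (RK4, 1-minute internal step), subsamples glucose onto
#' the 5-minute CGM grid and adds autocorrelated sensor noise. The output is
#' defect free (all slots valid); use [inject_missingness()],
#' [inject_outliers()] or [inject_frozen_sensor()] to add clinical-style
#' defects.
#'
#' @param scenario A [sim_scenario()].
#' @param subject_id Label for the simulated subject.
#' @param start Start time of the record (first slot is `start`).
#' @return A [subject_series()] with `n_days * 288` slots.
#' @details Determinism: the same `(scenario, seed)` produces a bitwise
#'   identical series. Meal events deposit their carbohydrate in the gut
#'   compartment and raise glucose; boluses enter the subcutaneous insulin
#'   chain and lower it. Glucose is floored at 20 mg/dL so the positivity
#'   invariant holds even under extreme insulin stacking.
#' @examples
#' s <- simulate_subject(sim_scenario(n_days = 2, seed = 7))
#' s
#' @export
simulate_subject <- function(scenario, subject_id = "sim01",
                             start = as.POSIXct("2024-01-01 00:00:00",
                                                tz = "UTC")) {
  if (!inherits(scenario, "sim_scenario"))
    stopf("`scenario` must be a sim_scenario")
  check_physiology(scenario$physiology)
  n_days <- scenario$n_days
  n_min <- n_days * 24L * 60L
  n_slots <- n_days * SLOTS_PER_DAY
  with_seed(scenario$seed, {
    meal_mg <- numeric(n_min)
    bolus_mU <- numeric(n_min)
    meal_slot_g <- numeric(n_slots)
    bolus_slot_u <- numeric(n_slots)
    anchors <- meal_anchor_minutes(scenario$meals_per_day)
    for (day in seq_len(n_days)) {
      day0 <- (day - 1L) * 1440L
      if (length(anchors)) {
        times <- round(anchors + stats::rnorm(length(anchors), 0,
                                              scenario$meal_time_std))
        times <- pmin(pmax(times, 0), 1439)
        sizes <- scenario$meal_size_mean *
          (1 + scenario$meal_size_cv * stats::rnorm(length(anchors)))
        sizes <- pmax(sizes, 1)
        for (i in seq_along(times)) {
          tmin <- day0 + times[i] + 1L
          meal_mg[tmin] <- meal_mg[tmin] + sizes[i] * 1000
          sl <- day0 %/% SLOT_MIN + times[i] %/% SLOT_MIN + 1L
          meal_slot_g[sl] <- meal_slot_g[sl] + sizes[i]
        }
      }
      nb <- scenario$boluses_per_day_range[1]
      if (scenario$boluses_per_day_range[2] > nb)
        nb <- sample(scenario$boluses_per_day_range[1]:
                       scenario$boluses_per_day_range[2], 1L)
      if (nb > 0 && length(anchors)) {
        anchor_pick <- sample(seq_along(anchors), nb, replace = TRUE)
        btimes <- round(anchors[anchor_pick] +
                          stats::rnorm(nb, 0, scenario$bolus_time_jitter_sd))
        btimes <- pmin(pmax(btimes, 0), 1439)
        doses <- scenario$bolus_dose_mean *
          (1 + scenario$bolus_dose_cv * stats::rnorm(nb))
        doses <- pmax(doses, 0.1)
        for (i in seq_len(nb)) {
          tmin <- day0 + btimes[i] + 1L
          bolus_mU[tmin] <- bolus_mU[tmin] + doses[i] * 1000
          sl <- day0 %/% SLOT_MIN + btimes[i] %/% SLOT_MIN + 1L
          bolus_slot_u[sl] <- bolus_slot_u[sl] + doses[i]
        }
      }
    }
    g_min <- integrate_minimal_model(n_min, meal_mg, bolus_mU,
                                     scenario$physiology)
    g <- g_min[seq(SLOT_MIN, n_min, by = SLOT_MIN)]
    if (scenario$sensor_noise_sd > 0) {
      rho <- scenario$noise_ar1
      innov <- stats::rnorm(n_slots, 0,
                            scenario$sensor_noise_sd * sqrt(1 - rho^2))
      noise <- stats::filter(innov, rho, method = "recursive")
      g <- g + as.numeric(noise)
    }
    g <- pmax(g, 20)
    tm <- start + 60 * SLOT_MIN * (seq_len(n_slots) - 1L)
    subject_series(subject_id, tm, g, bolus_slot_u, meal_slot_g,
                   valid = rep(TRUE, n_slots))
  })
}

#' Simulate a synthetic cohort
#'
#' Generates `n_subjects` subjects from a base scenario. Each subject gets its
#' own derived seed and, to emulate inter-subject physiological variability,
#' its minimal-model parameters `p1`, `p3`, `Gb` and `kgut` are jittered
#' log-normally with coefficient of variation `physiology_cv`.
#'
#' @param n_subjects Number of subjects.
#' @param scenario Base [sim_scenario()]; per-subject seeds are derived from
#'   its `seed`.
#' @param physiology_cv CV of the per-subject physiology jitter (default 0.1).
#' @return A list of [subject_series()].
#' @export
simulate_cohort <- function(n_subjects, scenario, physiology_cv = 0.1) {
  if (!is_count(n_subjects)) stopf("`n_subjects` must be a positive integer")
  lapply(seq_len(n_subjects), function(i) {
    sc <- scenario
    sc$seed <- scenario$seed + 1000L * i
    sc$physiology <- with_seed(sc$seed + 1L, {
      ph <- scenario$physiology
      for (nm in c("p1", "p3", "Gb", "kgut"))
        ph[[nm]] <- ph[[nm]] * exp(stats::rnorm(1, 0, physiology_cv))
      ph
    })
    simulate_subject(sc, subject_id = sprintf("sim%02d", i))
  })
}

#' Scenario YAML round trip
#'
#' @param scenario A [sim_scenario()].
#' @param path YAML file path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns a [sim_scenario()].
#' @export
write_scenario_yaml <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  ph <- if (is.null(raw$physiology)) default_physiology() else
    utils::modifyList(default_physiology(), raw$physiology)
  do.call(sim_scenario, c(raw[setdiff(names(raw), "physiology")],
                          list(physiology = ph)))
}
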