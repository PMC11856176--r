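# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic development law for simulations
#'
#' A complete immature-stage thermal-summation law used by the scenario
#' generators: cumulative durations at 26.2 degC of 24/47/95/166/243 h to
#' enter instar1 through puparium (an urban *L. sericata*-like pace),
#' converted to ADH thresholds above a 10 degC base.
#'
#' @param species Species label to attach.
#' @param base_temp_C Base temperature (°C).
#' @return A `development_dataset`.
#' @export
synthetic_dataset <- function(species = "Lucilia sericata", base_temp_C = 10) {
  development_dataset(
    species = species, base_temp_C = base_temp_C,
    constant_table = tibble::tibble(
      temp_C = 26.2,
      stage = c("instar1", "instar2", "instar3", "post_feeding", "puparium"),
      cumulative_hours = c(24, 47, 95, 166, 243)
    ),
    provenance = "Synthetic blowfly development law for simulation (L. sericata-like pace)"
  )
}

#' Configure a synthetic death-scene scenario
#'
#' Bundles every knob of the synthetic-data generators: the diurnal station
#' temperature model, the station-to-scene relation with covariate effects,
#' observation noise, and the simulated death/colonization timing. Defaults
#' emulate an early-autumn urban indoor scene: an outdoor station cycling
#' 21.5 +/- 3.6 degC feeding a damped indoor scene around 24.5 +/- 0.8 degC,
#' no rainfall, and a logger-accuracy noise floor of 0.5 degC.
#'
#' @param seed RNG seed; every generator is bit-reproducible under it.
#' @param days Length of the paired series in days (>= 2, so that the 48-row
#'   fitting precondition holds).
#' @param start_time First timestamp of the paired window.
#' @param diurnal_mean_C,diurnal_amplitude_C Station sinusoid (period 24 h,
#'   afternoon peak).
#' @param station_noise_sd_C Gaussian noise on the station readings.
#' @param scene_a,scene_b,scene_c Quadratic station-to-scene relation
#'   `scene = a + b*station + c*station^2`.
#' @param humidity_effect,wind_effect,rainfall_effect Additive covariate
#'   effects on the scene temperature (degC per unit of covariate).
#' @param noise_sd_C Gaussian noise on the scene logger readings.
#' @param rain_prob,rain_mean_mm Zero-inflated-exponential hourly rainfall:
#'   probability of a wet hour and mean depth when wet. Default dry.
#' @param true_death_time,true_pci_days Simulated death time and
#'   pre-colonization interval; colonization occurs at
#'   `true_death_time + true_pci_days`.
#' @param dataset Development law driving the simulated insects.
#' @param sampling_time When the evidence is collected.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            days = 4,
                            start_time = "2022-09-20 00:00",
                            diurnal_mean_C = 21.5, diurnal_amplitude_C = 3.6,
                            station_noise_sd_C = 0,
                            scene_a = 19.72, scene_b = 0.222, scene_c = 0,
                            humidity_effect = 0, wind_effect = 0, rainfall_effect = 0,
                            noise_sd_C = 0.5,
                            rain_prob = 0, rain_mean_mm = 2,
                            true_death_time = "2022-09-21 06:00",
                            true_pci_days = 0,
                            dataset = synthetic_dataset(),
                            sampling_time = "2022-09-23 12:00") {
  if (days < 2) rlang::abort("days must be >= 2 (48 paired hourly rows).")
  if (noise_sd_C < 0 || station_noise_sd_C < 0) rlang::abort("noise SDs must be non-negative.")
  structure(
    list(
      seed = as.integer(seed), days = days, start_time = parse_local_dt(start_time),
      diurnal_mean_C = diurnal_mean_C, diurnal_amplitude_C = diurnal_amplitude_C,
      station_noise_sd_C = station_noise_sd_C,
      scene_a = scene_a, scene_b = scene_b, scene_c = scene_c,
      humidity_effect = humidity_effect, wind_effect = wind_effect,
      rainfall_effect = rainfall_effect,
      noise_sd_C = noise_sd_C, rain_prob = rain_prob, rain_mean_mm = rain_mean_mm,
      true_death_time = parse_local_dt(true_death_time),
      true_pci_days = true_pci_days,
      dataset = dataset,
      sampling_time = parse_local_dt(sampling_time)
    ),
    class = "scenario_config"
  )
}

station_sinusoid <- function(config, timestamps) {
  hour_of_day <- (as.numeric(timestamps) %% 86400) / 3600
  config$diurnal_mean_C +
    config$diurnal_amplitude_C * sin(2 * pi * (hour_of_day - 9) / 24)
}

#' Generate an hourly weather-station series with covariates
#'
#' Sinusoidal diurnal temperature (afternoon peak) plus optional Gaussian
#' noise; humidity from a clipped normal, wind speed from a folded normal,
#' rainfall from a zero-inflated exponential. Bit-reproducible under the
#' config seed.
#'
#' @param config A [scenario_config()].
#' @param n_hours Number of hourly rows; defaults to `days * 24`.
#' @param start_time First timestamp; defaults to the config's.
#' @return Tibble `timestamp, station_temp_C, humidity_pct, wind_speed_ms,
#'   rainfall_mm`.
#' @export
gen_station_series <- function(config, n_hours = NULL, start_time = NULL) {
  n <- n_hours %||% (config$days * 24)
  t0 <- parse_local_dt(start_time %||% config$start_time)
  ts <- t0 + 3600 * (seq_len(n) - 1)
  with_rng(config$seed, {
    temp <- station_sinusoid(config, ts) + stats::rnorm(n, 0, config$station_noise_sd_C)
    humidity <- pmin(pmax(stats::rnorm(n, 65, 8), 20), 100)
    wind <- abs(stats::rnorm(n, 1.5, 0.8))
    wet <- stats::runif(n) < config$rain_prob
    rain <- ifelse(wet, stats::rexp(n, 1 / config$rain_mean_mm), 0)
    tibble::tibble(
      timestamp = ts, station_temp_C = temp,
      humidity_pct = humidity, wind_speed_ms = wind, rainfall_mm = rain
    )
  })
}

scene_truth <- function(config, station) {
  config$scene_a +
    config$scene_b * station$station_temp_C +
    config$scene_c * station$station_temp_C^2 +
    config$humidity_effect * station$humidity_pct +
    config$wind_effect * station$wind_speed_ms +
    config$rainfall_effect * station$rainfall_mm
}

#' Generate a paired logger/station series with known truth
#'
#' Scene temperature is the configured quadratic-plus-covariates transform
#' of the station series, plus Gaussian logger noise. The noise-free scene
#' values are recorded in the `truth` attribute for recovery tests.
#'
#' @inheritParams gen_station_series
#' @return Paired tibble (`timestamp, station_temp_C, scene_temp_C,
#'   humidity_pct, wind_speed_ms, rainfall_mm`) with attribute `truth`
#'   (list: coefficients, effects, noise-free `scene_true`).
#' @export
gen_paired_series <- function(config, n_hours = NULL, start_time = NULL) {
  station <- gen_station_series(config, n_hours, start_time)
  truth_scene <- scene_truth(config, station)
  noise <- with_rng(config$seed + 1L, stats::rnorm(nrow(station), 0, config$noise_sd_C))
  out <- station |>
    dplyr::mutate(scene_temp_C = truth_scene + noise) |>
    dplyr::relocate("timestamp", "station_temp_C", "scene_temp_C")
  attr(out, "truth") <- list(
    a = config$scene_a, b = config$scene_b, c = config$scene_c,
    humidity_effect = config$humidity_effect,
    wind_effect = config$wind_effect,
    rainfall_effect = config$rainfall_effect,
    scene_true = truth_scene
  )
  out
}

#' Simulate a colonized death scene as a case with known ground truth
#'
#' Places colonization at `true_death_time + true_pci_days`, develops the
#' simulated insects forward along the noise-free scene temperature series,
#' and assembles a `pmi_case` whose specimen roster carries the oldest stage
#' reached by the sampling time. By default the collection time is snapped
#' to that stage's entry time — the PMI-min convention dates the oldest
#' stage's entry at collection, so snapping makes exact recovery of the
#' colonization time a property of the back-calculation rather than of
#' sampling luck; pass `snap = FALSE` to keep the raw sampling time and
#' study the stage-discreteness censoring instead.
#'
#' @param config A [scenario_config()]; `sampling_time` must lie after
#'   colonization.
#' @param snap Snap collection to the oldest reached stage's entry time.
#' @return List with `case` (a `pmi_case`) and `truth` (death/colonization
#'   times, PCI, oldest stage, scene series, window mean temperature).
#' @export
gen_case <- function(config, snap = TRUE) {
  colonization <- config$true_death_time + config$true_pci_days * 86400
  if (as.numeric(config$sampling_time) <= as.numeric(colonization)) {
    rlang::abort("Degenerate scenario: sampling_time precedes colonization (death + PCI).")
  }
  t0 <- as.POSIXct(floor(as.numeric(config$true_death_time) / 3600) * 3600 - 7200,
    origin = "1970-01-01", tz = "UTC"
  )
  n <- ceiling(hours_between(t0, config$sampling_time)) + 4
  station <- gen_station_series(config, n_hours = n, start_time = t0)
  scene <- hourly_series(station$timestamp, scene_truth(config, station))

  dev <- forward_simulate(config$dataset, scene, colonization)
  reached <- dev[as.numeric(dev$entry_time) <= as.numeric(config$sampling_time) + 1e-6, ]
  oldest <- reached[nrow(reached), ]
  collection <- if (snap) oldest$entry_time else config$sampling_time

  roster <- specimens(
    sample_id = paste0("SYN-", seq_len(3)),
    species = rep(config$dataset$species, 3),
    stage = rep(oldest$stage, 3)
  )
  window_mean <- mean(scene$temp_C[
    as.numeric(scene$timestamp) >= as.numeric(colonization) - 3600 &
      as.numeric(scene$timestamp) <= as.numeric(collection)
  ])
  case <- pmi_case(
    case_id = sprintf("synthetic-%d", config$seed),
    discovery_time = collection,
    collection_time = collection,
    location_class = "indoor",
    specimens = roster,
    last_known_activity = config$true_death_time,
    reference_granularity = "minute",
    corrected_mean_temp_C = window_mean
  )
  list(
    case = case,
    truth = list(
      death_time = config$true_death_time,
      colonization_time = colonization,
      pci_days = config$true_pci_days,
      oldest_stage = oldest$stage,
      collection_time = collection,
      scene_series = scene,
      window_mean_C = window_mean
    )
  )
}
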