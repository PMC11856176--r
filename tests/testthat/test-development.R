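test_that("ADH accumulation matches hand arithmetic and clamps at the base", {
  s <- constant_series(26.2, "2022-08-01 00:00", "2022-08-02 00:00")
  expect_equal(adh_accumulate(s, 10, "2022-08-01 00:00", "2022-08-01 10:00"), 162)
  # at the base temperature nothing accumulates
  sb <- constant_series(10, "2022-08-01 00:00", "2022-08-02 00:00")
  expect_equal(adh_accumulate(sb, 10, "2022-08-01 02:00", "2022-08-01 20:00"), 0)
  # below-base hours contribute zero, not negative
  cold <- constant_series(5, "2022-08-01 00:00", "2022-08-02 00:00")
  expect_equal(adh_accumulate(cold, 10, "2022-08-01 00:00", "2022-08-02 00:00"), 0)
  # fractional hours prorate linearly
  expect_equal(adh_accumulate(s, 10, "2022-08-01 00:30", "2022-08-01 01:30"), 16.2)
})

test_that("ADH on a sawtooth profile agrees with 1-minute brute-force integration", {
  ts <- seq(as.POSIXct("2022-07-01 00:00", tz = "UTC"), by = 3600, length.out = 96)
  saw <- hourly_series(ts, 15 + (seq_along(ts) %% 12))
  for (win in list(
    c("2022-07-01 03:00", "2022-07-02 17:00"),
    c("2022-07-01 00:17", "2022-07-03 21:43"),
    c("2022-07-02 12:00", "2022-07-02 12:00")
  )) {
    expect_equal(
      adh_accumulate(saw, 14, win[1], win[2]),
      adh_brute(saw, 14, win[1], win[2]),
      tolerance = 0.02
    )
  }
})

test_that("ADH is additive over adjacent windows and monotone in window length", {
  cfg <- scenario_config(seed = 3, days = 5, noise_sd_C = 0)
  st <- gen_station_series(cfg)
  s <- hourly_series(st$timestamp, st$station_temp_C)
  t0 <- st$timestamp[5] + 1234
  t1 <- t0 + 3600 * 20 + 567
  t2 <- t1 + 3600 * 30
  a01 <- adh_accumulate(s, 18, t0, t1)
  a12 <- adh_accumulate(s, 18, t1, t2)
  a02 <- adh_accumulate(s, 18, t0, t2)
  expect_equal(a01 + a12, a02, tolerance = 1e-9)
  expect_gte(a02, a01)
  expect_error(adh_accumulate(s, 18, t0 - 86400 * 30, t1), "covers")
})

test_that("thresholds derive from constant-temperature duration tables", {
  tbl <- tibble::tibble(temp_C = 28.9, stage = "instar3", cumulative_hours = 46)
  thr <- thresholds_from_constant_table(tbl, base_temp_C = 10)
  expect_equal(thr$cumulative_adh[thr$stage == "instar3"], 46 * 18.9) # 869.4

  # a table consistent with one ADH law at two temperatures has zero spread
  law <- tibble::tibble(
    temp_C = rep(c(20, 30), each = 2),
    stage = rep(c("instar1", "instar2"), 2),
    cumulative_hours = c(100 / 10, 300 / 10, 100 / 20, 300 / 20)
  )
  thr2 <- thresholds_from_constant_table(law, base_temp_C = 10)
  expect_equal(thr2$cumulative_adh, c(100, 300))
  expect_equal(attr(thr2, "spread")$spread_adh, c(0, 0))

  expect_error(
    thresholds_from_constant_table(
      tibble::tibble(
        temp_C = 25, stage = c("instar1", "instar2"),
        cumulative_hours = c(50, 40)
      ), 10
    ),
    "increasing"
  )
  expect_error(thresholds_from_constant_table(tbl, base_temp_C = 30), "below")
})

test_that("dataset invariants: egg at zero, strictly increasing thresholds, provenance", {
  expect_error(
    development_dataset("X sp", 10,
      thresholds = tibble::tibble(stage = c("instar1", "instar2"), cumulative_adh = c(5, 5)),
      provenance = "t"
    ),
    "increasing"
  )
  expect_error(
    development_dataset("X sp", 10,
      thresholds = tibble::tibble(stage = "egg", cumulative_adh = 3),
      provenance = "t"
    ),
    "egg"
  )
  expect_error(
    development_dataset("X sp", 10,
      thresholds = tibble::tibble(stage = "instar1", cumulative_adh = 10)
    ),
    "provenance"
  )
})

test_that("stage_at honours the closed-left boundary convention", {
  ds <- tiny_dataset()
  expect_equal(stage_at(ds, 0), "egg")
  expect_equal(stage_at(ds, 99.999), "egg")
  expect_equal(stage_at(ds, 100), "instar1")
  expect_equal(stage_at(ds, 300.0001), "instar2")
  # brute-force linear-scan oracle over random ADH values
  scan <- function(adh) {
    thr <- ds$thresholds
    as.character(thr$stage[max(which(thr$cumulative_adh <= adh + 1e-9))])
  }
  set.seed(1)
  for (adh in runif(50, 0, 400)) expect_equal(stage_at(ds, adh), scan(adh))
})

test_that("forward simulation hits stage entries and flags truncated series", {
  ds <- tiny_dataset()
  s <- constant_series(20, "2022-07-01 00:00", "2022-07-03 00:00")
  tl <- forward_simulate(ds, s, "2022-07-01 00:00")
  # at 20 degC, rate 10 ADH/h: instar1 at 10 h, instar2 at 30 h
  expect_equal(tl$stage, c("egg", "instar1", "instar2"))
  expect_equal(hours_diff <- as.numeric(tl$entry_time - tl$entry_time[1], units = "hours"), c(0, 10, 30))
  expect_true(attr(tl, "complete"))
  expect_true(all(diff(as.numeric(tl$entry_time)) > 0))

  short <- constant_series(20, "2022-07-01 00:00", "2022-07-01 15:00")
  tl2 <- forward_simulate(ds, short, "2022-07-01 00:00")
  expect_false(attr(tl2, "complete"))
  expect_equal(tl2$stage, c("egg", "instar1"))

  # temperatures at the base: nothing beyond egg, ever
  frozen <- constant_series(10, "2022-07-01 00:00", "2022-07-05 00:00")
  tl3 <- forward_simulate(ds, frozen, "2022-07-01 00:00")
  expect_equal(tl3$stage, "egg")
})

test_that("backtracking reduces to the closed form at constant temperature", {
  fx <- busan_case(2)
  ds <- fx$datasets[["Lucilia sericata"]]
  at <- as.POSIXct("2022-08-12 14:50", tz = "UTC")
  s <- constant_series(28.9, at - 100 * 3600, at)
  bt <- backtrack_oviposition(ds, s, "instar3", at)
  closed <- at - 3600 * duration_at_constant(ds, "instar3", 28.9)
  expect_equal(bt$oviposition_time, closed)
  expect_equal(format(bt$oviposition_time, "%Y-%m-%d %H:%M"), "2022-08-09 03:50")

  # egg observed: oviposition equals the observation time
  bt0 <- backtrack_oviposition(ds, s, "egg", at)
  expect_equal(bt0$oviposition_time, at)

  expect_error(
    backtrack_oviposition(ds, constant_series(28.9, at - 10 * 3600, at), "instar3", at),
    "degree hours"
  )
})

test_that("forward and backward ADH walks are mutual inverses on varying series", {
  ds <- synthetic_dataset()
  for (seed in 1:8) {
    cfg <- scenario_config(
      seed = seed, days = 22,
      diurnal_mean_C = 15 + seed, diurnal_amplitude_C = 1 + (seed %% 4),
      start_time = "2022-09-01 00:00", noise_sd_C = 0
    )
    st <- gen_station_series(cfg)
    s <- hourly_series(st$timestamp, st$station_temp_C + 8) # keep well above base
    ovi <- st$timestamp[3] + 1800
    tl <- forward_simulate(ds, s, ovi)
    reached <- tl[nrow(tl), ]
    bt <- backtrack_oviposition(ds, s, reached$stage, reached$entry_time)
    expect_lt(abs(hours_between(bt$oviposition_time, ovi)), 1)
    # and the backtracked timeline reproduces the forward entries
    gap_h <- abs(as.numeric(bt$timeline$entry_time) -
      as.numeric(tl$entry_time[seq_len(nrow(bt$timeline))])) / 3600
    expect_lt(max(gap_h), 1)
  }
})

test_that("development dataset YAML round-trips through the reader", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    species = "Lucilia sericata", base_temp_C = 10,
    provenance = "roundtrip fixture",
    stages = list(
      list(stage = "instar1", cumulative_adh = 100),
      list(stage = "instar2", cumulative_adh = 300)
    )
  ), path)
  ds <- read_development_dataset(path)
  expect_equal(ds$thresholds$cumulative_adh, c(0, 100, 300))
  expect_equal(ds$base_temp_C, 10)
})
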