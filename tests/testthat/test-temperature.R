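test_that("quadratic fit recovers exact coefficients from noise-free quadratics", {
  paired <- quadratic_paired(1, 0.9, 0.01)
  m <- fit_quadratic(paired)
  expect_equal(tidy(m)$estimate, c(1, 0.9, 0.01), tolerance = 1e-8)
  expect_lt(max(abs(residuals(m$fit))), 1e-9)
  # cross-validated diagnostics are also numerically zero
  expect_lt(m$rmse_C, 1e-8)
})

test_that("identity pairing gives the identity quadratic with zero MAD/RMSE", {
  paired <- quadratic_paired(0, 1, 0)
  m <- fit_quadratic(paired)
  expect_equal(tidy(m)$estimate, c(0, 1, 0), tolerance = 1e-8)
  ev <- evaluate_model(m, paired)
  expect_equal(ev$mad_C, 0, tolerance = 1e-10)
  expect_equal(ev$rmse_C, 0, tolerance = 1e-10)
})

test_that("quadratic coefficients fall within 3 standard errors of truth across seeds", {
  truth <- c(1, 0.9, 0.01)
  hits <- vapply(1:100, function(seed) {
    paired <- quadratic_paired(1, 0.9, 0.01, n = 72, noise_sd = 0.5, seed = seed)
    td <- tidy(fit_quadratic(paired, cv = FALSE))
    all(abs(td$estimate - truth) <= 3 * td$std.error)
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("fitting preconditions: short series and degenerate designs are rejected", {
  paired <- quadratic_paired(0, 1, 0, n = 30)
  expect_error(fit_quadratic(paired), "2 days")
  flat <- tibble::tibble(
    timestamp = seq(as.POSIXct("2022-06-01", tz = "UTC"), by = 3600, length.out = 72),
    station_temp_C = 20, scene_temp_C = rnorm(72)
  )
  expect_error(fit_quadratic(flat), "identical")
  gappy <- quadratic_paired(0, 1, 0)[-10, ]
  expect_error(fit_quadratic(gappy), "spacing")
})

test_that("MAD and RMSE follow their definitions and the Jensen ordering", {
  # forced arithmetic: errors (+1, -2) -> MAD 1.5, RMSE sqrt(2.5)
  paired <- tibble::tibble(
    timestamp = seq(as.POSIXct("2022-06-01", tz = "UTC"), by = 3600, length.out = 2),
    station_temp_C = c(10, 20), scene_temp_C = c(10, 20)
  )
  shifted <- dplyr::mutate(paired, scene_temp_C = scene_temp_C - c(1, -2))
  identity_model <- fit_quadratic(quadratic_paired(0, 1, 0))
  ev <- evaluate_model(identity_model, shifted)
  expect_equal(ev$mad_C, 1.5)
  expect_equal(ev$rmse_C, sqrt(2.5))

  # property: RMSE >= MAD >= 0 on arbitrary noisy data
  for (seed in 1:10) {
    noisy <- quadratic_paired(2, 0.8, 0.02, noise_sd = 1, seed = seed)
    ev <- evaluate_model(identity_model, noisy)
    expect_gte(ev$rmse_C, ev$mad_C)
    expect_gte(ev$mad_C, 0)
  }
})

test_that("SVR learns the identity mapping and constant targets", {
  paired <- quadratic_paired(0, 1, 0)
  m <- fit_svr(paired)
  ev <- evaluate_model(m, paired)
  expect_lte(ev$mad_C, 0.1 + 1e-6) # within the epsilon tube

  const <- dplyr::mutate(quadratic_paired(0, 1, 0), scene_temp_C = 23.7)
  mc <- fit_svr(const)
  pred <- predict(mc, const)
  expect_lt(max(abs(pred - 23.7)), 0.15)
})

test_that("SVR is deterministic under a fixed config and errors on absent covariates", {
  paired <- quadratic_paired(1, 0.9, 0.01, noise_sd = 0.3)
  m1 <- fit_svr(paired, features = "humidity_pct")
  m2 <- fit_svr(paired, features = "humidity_pct")
  expect_identical(predict(m1, paired), predict(m2, paired))
  expect_warning(fit_svr(paired, features = "pressure_hPa"), "pressure_hPa")
})

test_that("SVR beats the quadratic on held-out hours when a covariate drives the scene", {
  cfg <- scenario_config(
    seed = 7, days = 6,
    scene_a = 2, scene_b = 0.9, scene_c = 0,
    rainfall_effect = -0.5, rain_prob = 0.4, rain_mean_mm = 3,
    noise_sd_C = 0.1
  )
  paired <- gen_paired_series(cfg)
  train <- paired[1:96, ]
  test <- paired[97:144, ]
  quad <- fit_quadratic(train, cv = FALSE)
  svr <- fit_svr(train, features = "rainfall_mm", cv = FALSE)
  mad_q <- evaluate_model(quad, test)$mad_C
  mad_s <- evaluate_model(svr, test)$mad_C
  expect_lt(mad_s, mad_q)
})

test_that("model selection minimizes RMSE with MAD and simplicity tie-breaks", {
  fake <- function(kind, rmse, mad) {
    structure(list(kind = kind, rmse_C = rmse, mad_C = mad), class = "correction_model")
  }
  expect_equal(select_model(list(fake("quadratic", 1.2, 1.0), fake("svr", 0.8, 0.7)))$kind, "svr")
  expect_equal(select_model(list(fake("svr", 0.8, 0.7)))$kind, "svr")
  expect_equal(select_model(list(fake("svr", 1.0, 0.8), fake("quadratic", 1.0, 0.8)))$kind, "quadratic")
  expect_equal(select_model(list(fake("svr", 1.0, 0.6), fake("quadratic", 1.0, 0.8)))$kind, "svr")
  expect_error(select_model(list()), "No candidate")
})

test_that("retrodiction applies the model hourly and reports the window mean", {
  paired <- quadratic_paired(0, 1, 0)
  m <- fit_quadratic(paired)
  out <- retrodict(m, paired)
  expect_equal(out$temp_C, paired$station_temp_C, tolerance = 1e-8)
  expect_equal(attr(out, "mean_C"), mean(paired$station_temp_C), tolerance = 1e-8)

  const <- dplyr::mutate(paired, station_temp_C = 26.2)[, c("timestamp", "station_temp_C")]
  expect_equal(attr(retrodict(m, const), "mean_C"), 26.2, tolerance = 1e-8)

  gappy <- paired[-30, ]
  expect_error(retrodict(m, gappy), "spacing")
})

test_that("noise-free generator truth is recovered end to end within logger accuracy", {
  cfg <- scenario_config(seed = 11, days = 4, scene_a = 3, scene_b = 0.85, scene_c = 0.004, noise_sd_C = 0)
  paired <- gen_paired_series(cfg)
  m <- fit_quadratic(paired)
  out <- retrodict(m, paired)
  truth <- attr(paired, "truth")$scene_true
  expect_lt(max(abs(out$temp_C - truth)), 1e-6)

  # with noise at the logger's own accuracy the window mean stays within 0.5 degC
  cfg2 <- scenario_config(seed = 12, days = 4, scene_a = 3, scene_b = 0.85, scene_c = 0.004, noise_sd_C = 0.5)
  paired2 <- gen_paired_series(cfg2)
  m2 <- fit_quadratic(paired2)
  truth_mean <- mean(attr(paired2, "truth")$scene_true)
  expect_lt(abs(attr(retrodict(m2, paired2), "mean_C") - truth_mean), 0.5)
})
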