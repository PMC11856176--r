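# Shared in-code fixtures for the test suite.

# Tiny two-stage development law: 100 ADH to instar1, 300 to instar2,
# base 10 degC. Small numbers keep hand arithmetic easy.
tiny_dataset <- function() {
  development_dataset(
    species = "Lucilia sericata", base_temp_C = 10,
    thresholds = tibble::tibble(
      stage = c("instar1", "instar2"),
      cumulative_adh = c(100, 300)
    ),
    provenance = "test fixture"
  )
}

# Paired series generated from an exact quadratic with optional noise.
quadratic_paired <- function(a, b, c, n = 72, noise_sd = 0, seed = 42,
                             start = "2022-06-01 00:00") {
  cfg <- scenario_config(
    seed = seed, days = ceiling(n / 24),
    start_time = start,
    diurnal_mean_C = 22, diurnal_amplitude_C = 5,
    scene_a = a, scene_b = b, scene_c = c,
    noise_sd_C = noise_sd
  )
  gen_paired_series(cfg, n_hours = n)
}

# Brute-force ADH oracle: Riemann sum of max(T - base, 0) at 1-second
# resolution, treating each hourly reading as constant over its block.
adh_brute <- function(series, base, from, to) {
  from <- as.POSIXct(from, tz = "UTC")
  to <- as.POSIXct(to, tz = "UTC")
  if (as.numeric(to) - as.numeric(from) < 1) {
    return(0)
  }
  secs <- seq(as.numeric(from), as.numeric(to) - 0.5, by = 1)
  block <- findInterval(secs, as.numeric(series$timestamp))
  sum(pmax(series$temp_C[block] - base, 0)) / 3600
}
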