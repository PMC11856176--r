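#' Build an hourly temperature series
#'
#' @param timestamps Hourly local datetimes (strings or POSIXct), strictly
#'   increasing at fixed 1 h spacing.
#' @param temp_C Temperatures (°C), one per hour. Each reading is treated as
#'   constant over its hour block `[t, t + 1h)` — the logger's recording
#'   interval.
#' @return Tibble `timestamp, temp_C`.
#' @export
hourly_series <- function(timestamps, temp_C) {
  ts <- parse_local_dt(timestamps)
  if (length(ts) != length(temp_C)) rlang::abort("timestamps and temp_C must have equal length.")
  if (length(ts) > 1) {
    gaps <- diff(as.numeric(ts)) / 3600
    if (any(abs(gaps - 1) > 1e-6)) {
      rlang::abort("Timestamps must be strictly increasing at a fixed 1 h spacing.")
    }
  }
  tibble::tibble(timestamp = ts, temp_C = as.numeric(temp_C))
}

#' Constant-temperature hourly series covering a window
#'
#' Convenience constructor for the constant-mean mode used when only a
#' corrected average scene temperature is available for a case.
#'
#' @param temp_C Constant temperature (°C).
#' @param from,to Window to cover (the series extends to full hours around it).
#' @return Tibble `timestamp, temp_C`.
#' @export
constant_series <- function(temp_C, from, to) {
  from <- parse_local_dt(from)
  to <- parse_local_dt(to)
  start <- as.POSIXct(floor(as.numeric(from) / 3600) * 3600, origin = "1970-01-01", tz = "UTC")
  n <- ceiling(hours_between(start, to)) + 1
  hourly_series(start + 3600 * (seq_len(n) - 1), rep(as.numeric(temp_C), n))
}

# Hour blocks with degree-hour accumulation rates above base. Block i spans
# [timestamp_i, timestamp_i + 1h) at rate max(temp_i - base, 0) degree-hours
# per hour.
series_blocks <- function(series, base_temp_C) {
  list(
    start = as.numeric(series$timestamp),
    rate = pmax(series$temp_C - base_temp_C, 0)
  )
}

series_coverage_check <- function(series, from, to) {
  t0 <- as.numeric(series$timestamp[1])
  t1 <- as.numeric(series$timestamp[nrow(series)]) + 3600
  if (as.numeric(from) < t0 - 1e-6 || as.numeric(to) > t1 + 1e-6) {
    rlang::abort(sprintf(
      "Temperature series covers [%s, %s) but the window [%s, %s] was requested.",
      format_local_dt(series$timestamp[1]),
      format_local_dt(series$timestamp[nrow(series)] + 3600),
      format_local_dt(from), format_local_dt(to)
    ))
  }
}

#' Accumulated degree hours over a window
#'
#' Computes the thermal-summation quantity
#' \eqn{\sum_h \max(T_h - T_{base}, 0) \cdot \Delta t} over `[from, to]`,
#' with temperatures constant over each hour block and fractional first/last
#' hours prorated linearly.
#'
#' @param series Hourly series from [hourly_series()] covering `[from, to]`.
#' @param base_temp_C Developmental base temperature \eqn{T_{base}} (°C);
#'   hours at or below it contribute nothing.
#' @param from,to Window endpoints (`from <= to`).
#' @return Accumulated degree hours (°C·h), non-negative.
#' @export
#' @examples
#' s <- constant_series(26.2, "2022-08-01 00:00", "2022-08-02 00:00")
#' adh_accumulate(s, 10, "2022-08-01 00:00", "2022-08-01 10:00") # 162
adh_accumulate <- function(series, base_temp_C, from, to) {
  from <- parse_local_dt(from)
  to <- parse_local_dt(to)
  if (as.numeric(to) < as.numeric(from)) rlang::abort("`from` must not exceed `to`.")
  series_coverage_check(series, from, to)
  b <- series_blocks(series, base_temp_C)
  lo <- pmax(b$start, as.numeric(from))
  hi <- pmin(b$start + 3600, as.numeric(to))
  overlap_h <- pmax(hi - lo, 0) / 3600
  sum(b$rate * overlap_h)
}

#' Derive ADH stage thresholds from constant-temperature durations
#'
#' Published development datasets often tabulate cumulative durations from
#' oviposition to each stage entry at constant rearing temperatures. Under
#' thermal summation, the ADH threshold for a stage is
#' `duration_hours * (T - T_base)`. When the table holds several
#' temperatures, the per-temperature thresholds are averaged and their
#' spread (max - min per stage) is reported as a consistency diagnostic: a
#' large spread means the data do not follow a single linear ADH law.
#'
#' @param constant_table Tibble with columns `temp_C`, `stage`,
#'   `cumulative_hours` (duration from oviposition to stage entry).
#' @param base_temp_C Base temperature (°C); must be below every `temp_C`.
#' @return Tibble `stage, cumulative_adh` (ordered by stage) with a `spread`
#'   attribute (tibble `stage, spread_adh`).
#' @export
thresholds_from_constant_table <- function(constant_table, base_temp_C) {
  tbl <- tibble::as_tibble(constant_table)
  stopifnot(all(c("temp_C", "stage", "cumulative_hours") %in% names(tbl)))
  if (any(tbl$temp_C <= base_temp_C)) {
    rlang::abort("base_temp_C must be below every constant rearing temperature.")
  }
  tbl <- dplyr::mutate(tbl, stage = stage_factor(.data$stage))
  ok <- tbl |>
    dplyr::group_by(.data$temp_C) |>
    dplyr::arrange(.data$stage, .by_group = TRUE) |>
    dplyr::summarise(
      mono = all(diff(.data$cumulative_hours) > 0) || dplyr::n() == 1,
      .groups = "drop"
    )
  if (!all(ok$mono)) {
    rlang::abort("Cumulative durations must be strictly increasing along the stage order at each temperature.")
  }
  per_temp <- dplyr::mutate(tbl, adh = .data$cumulative_hours * (.data$temp_C - base_temp_C))
  out <- per_temp |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      cumulative_adh = mean(.data$adh),
      spread_adh = max(.data$adh) - min(.data$adh),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$stage)
  thresholds <- dplyr::select(out, "stage", "cumulative_adh")
  attr(thresholds, "spread") <- dplyr::select(out, "stage", "spread_adh")
  thresholds
}

#' Assemble a species development dataset
#'
#' Bundles a species' base temperature with its cumulative ADH stage-entry
#' thresholds (degree hours from oviposition required to *enter* each
#' stage; `egg` is always 0). Thresholds may be given directly or derived
#' from a constant-temperature duration table.
#'
#' @param species Canonical binomial.
#' @param base_temp_C Base (developmental threshold) temperature, °C.
#' @param thresholds Tibble `stage, cumulative_adh`, strictly increasing
#'   along the stage order. An `egg` row at 0 is added if absent.
#' @param provenance Citation or origin string (mandatory).
#' @param constant_table Alternative to `thresholds`: a duration table for
#'   [thresholds_from_constant_table()].
#' @return Object of class `development_dataset`.
#' @export
development_dataset <- function(species, base_temp_C, thresholds = NULL,
                                provenance, constant_table = NULL) {
  if (missing(provenance) || !nzchar(provenance)) {
    rlang::abort("A provenance string is mandatory for development datasets.")
  }
  if (is.null(thresholds)) {
    if (is.null(constant_table)) rlang::abort("Supply thresholds or constant_table.")
    thresholds <- thresholds_from_constant_table(constant_table, base_temp_C)
  }
  thr <- tibble::as_tibble(thresholds) |>
    dplyr::mutate(stage = stage_factor(.data$stage)) |>
    dplyr::arrange(.data$stage)
  if (!"egg" %in% as.character(thr$stage)) {
    thr <- dplyr::bind_rows(tibble::tibble(stage = stage_factor("egg"), cumulative_adh = 0), thr)
  }
  if (thr$cumulative_adh[thr$stage == "egg"] != 0) {
    rlang::abort("threshold(egg) must be 0: eggs are present from oviposition.")
  }
  if (any(diff(thr$cumulative_adh) <= 0)) {
    rlang::abort("Stage thresholds must be strictly increasing along the stage order.")
  }
  structure(
    list(
      species = species, base_temp_C = base_temp_C,
      thresholds = thr, provenance = provenance,
      constant_table = if (!is.null(constant_table)) tibble::as_tibble(constant_table)
    ),
    class = "development_dataset"
  )
}

#' @export
print.development_dataset <- function(x, ...) {
  cat("<development_dataset> ", x$species, "  (T_base = ", x$base_temp_C, " °C)\n", sep = "")
  print(x$thresholds)
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read a development dataset from YAML
#'
#' Accepts either direct `stages: [{stage, cumulative_adh}, ...]` thresholds
#' or a `constant_table: [{temp_C, stage, cumulative_hours}, ...]` from
#' which thresholds are derived.
#'
#' @param path YAML file with fields `species`, `base_temp_C`, `provenance`
#'   and one of `stages` / `constant_table`.
#' @return A `development_dataset`.
#' @export
read_development_dataset <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- NULL
  ct <- NULL
  if (!is.null(y$stages)) {
    thr <- purrr::map_dfr(y$stages, tibble::as_tibble)
  } else if (!is.null(y$constant_table)) {
    ct <- purrr::map_dfr(y$constant_table, tibble::as_tibble)
  }
  development_dataset(
    species = y$species, base_temp_C = y$base_temp_C,
    thresholds = thr, constant_table = ct,
    provenance = y$provenance %||% ""
  )
}

threshold_for <- function(dataset, stage) {
  stage <- as.character(stage)
  hit <- dataset$thresholds$cumulative_adh[as.character(dataset$thresholds$stage) == stage]
  if (length(hit) == 0) {
    rlang::abort(paste0(
      "Dataset for ", dataset$species, " has no threshold for stage '", stage,
      "' (available: ", paste(as.character(dataset$thresholds$stage), collapse = ", "), ")."
    ))
  }
  hit
}

#' Developmental stage at a given accumulated degree-hour total
#'
#' Returns the latest stage whose entry threshold has been reached
#' (closed-left convention: an individual exactly at a threshold has entered
#' the stage).
#'
#' @param dataset A `development_dataset`.
#' @param adh Accumulated degree hours from oviposition (`>= 0`), scalar or
#'   vector.
#' @return Character vector of stage codes.
#' @export
stage_at <- function(dataset, adh) {
  stopifnot(all(adh >= 0))
  thr <- dataset$thresholds
  # count of thresholds reached; the epsilon keeps exact-threshold hits in
  # the stage they enter (closed-left)
  idx <- findInterval(adh, thr$cumulative_adh - 1e-9)
  idx <- pmin(pmax(idx, 1L), nrow(thr))
  as.character(thr$stage[idx])
}

# Piecewise-linear cumulative-ADH inversion on clipped hour blocks. Returns
# the earliest time (forward) at which the running ADH from `origin` reaches
# each target; NA where the series ends first.
adh_invert_forward <- function(series, base_temp_C, origin, targets) {
  origin <- as.numeric(origin)
  b <- series_blocks(series, base_temp_C)
  end <- b$start + 3600
  keep <- end > origin + 1e-9
  start <- pmax(b$start[keep], origin)
  end <- end[keep]
  rate <- b$rate[keep]
  inc <- rate * (end - start) / 3600
  cum <- cumsum(inc)
  purrr::map_dbl(targets, function(a) {
    if (a <= 1e-9) {
      return(origin)
    }
    i <- which(cum >= a - 1e-9)[1]
    if (is.na(i)) {
      return(NA_real_)
    }
    before <- if (i == 1) 0 else cum[i - 1]
    need <- a - before
    if (rate[i] <= 0) start[i] else start[i] + 3600 * need / rate[i]
  })
}

# Mirror image: walking backward from `origin`, the latest time t0 such that
# ADH over [t0, origin] equals each target. Attr "deficit" reports how many
# degree hours were still unconsumed when the series ran out.
adh_invert_backward <- function(series, base_temp_C, origin, targets) {
  origin <- as.numeric(origin)
  b <- series_blocks(series, base_temp_C)
  end <- pmin(b$start + 3600, origin)
  keep <- end > b$start + 1e-9 & b$start < origin
  start <- b$start[keep]
  end <- end[keep]
  rate <- b$rate[keep]
  # reverse so index 1 is the block adjacent to origin
  start <- rev(start)
  end <- rev(end)
  rate <- rev(rate)
  inc <- rate * (end - start) / 3600
  cum <- cumsum(inc)
  total <- if (length(cum)) cum[length(cum)] else 0
  out <- purrr::map_dbl(targets, function(a) {
    if (a <= 1e-9) {
      return(origin)
    }
    i <- which(cum >= a - 1e-9)[1]
    if (is.na(i)) {
      return(NA_real_)
    }
    before <- if (i == 1) 0 else cum[i - 1]
    need <- a - before
    if (rate[i] <= 0) end[i] else end[i] - 3600 * need / rate[i]
  })
  attr(out, "deficit") <- pmax(targets - total, 0)
  out
}

#' Forward-simulate development over a temperature series
#'
#' From an oviposition time, accumulates degree hours along the series and
#' records when each stage-entry threshold is first reached. If the series
#' ends before a threshold is reached, the returned timeline is partial and
#' flagged via its `complete` attribute.
#'
#' @param dataset A `development_dataset`.
#' @param series Hourly series covering from `oviposition` onward.
#' @param oviposition Oviposition datetime.
#' @return Tibble `stage, entry_time` for every stage entered (always
#'   includes `egg` at `oviposition`), attribute `complete` = TRUE when all
#'   dataset stages were reached.
#' @export
forward_simulate <- function(dataset, series, oviposition) {
  oviposition <- parse_local_dt(oviposition)
  series_coverage_check(series, oviposition, oviposition)
  thr <- dataset$thresholds
  times <- adh_invert_forward(series, dataset$base_temp_C, oviposition, thr$cumulative_adh)
  out <- tibble::tibble(
    stage = as.character(thr$stage),
    entry_time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
  )
  complete <- !anyNA(times)
  out <- out[!is.na(out$entry_time), , drop = FALSE]
  attr(out, "complete") <- complete
  out
}

#' Back-calculate oviposition time from an observed stage
#'
#' Walks backward from the observation time, consuming the observed stage's
#' entry threshold in accumulated degree hours, and returns the implied
#' oviposition time together with every intermediate stage-entry timestamp.
#' The convention is conservative: the oldest observed stage is assumed to
#' have been entered exactly at the observation time, so the result is the
#' latest oviposition compatible with the observation — the basis of the
#' minimum post-mortem interval.
#'
#' @param dataset A `development_dataset`.
#' @param series Hourly series covering a sufficient backward window from `at`.
#' @param observed_stage The oldest observed stage code.
#' @param at Observation (collection) datetime.
#' @return List with `oviposition_time` (POSIXct) and `timeline` (tibble
#'   `stage, entry_time` from egg at oviposition up to `observed_stage` at
#'   `at`).
#' @export
backtrack_oviposition <- function(dataset, series, observed_stage, at) {
  at <- parse_local_dt(at)
  observed_stage <- as.character(stage_factor(observed_stage))
  series_coverage_check(series, at, at)
  target <- threshold_for(dataset, observed_stage)
  raw <- adh_invert_backward(series, dataset$base_temp_C, at, target)
  if (is.na(raw)) {
    rlang::abort(sprintf(
      paste0(
        "Temperature series does not reach far enough back: %.1f degree hours ",
        "of the %.1f required for stage '%s' remain unconsumed at the start of ",
        "the series. Extend the series earlier."
      ),
      attr(raw, "deficit"), target, observed_stage
    ))
  }
  ovi <- as.POSIXct(as.numeric(raw[1]), origin = "1970-01-01", tz = "UTC")
  thr <- dataset$thresholds
  upto <- thr[thr$cumulative_adh <= target + 1e-9, , drop = FALSE]
  times <- adh_invert_forward(series, dataset$base_temp_C, ovi, upto$cumulative_adh)
  timeline <- tibble::tibble(
    stage = as.character(upto$stage),
    entry_time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
  )
  list(oviposition_time = ovi, timeline = timeline)
}

#' Development duration at a constant temperature
#'
#' Closed form of the thermal-summation model: the time from oviposition to
#' entry of `stage` at constant temperature `temp_C` is
#' `threshold(stage) / (temp_C - base)` hours.
#'
#' @param dataset A `development_dataset`.
#' @param stage Stage code.
#' @param temp_C Constant temperature, must exceed the base temperature.
#' @return Duration in hours.
#' @export
duration_at_constant <- function(dataset, stage, temp_C) {
  if (temp_C <= dataset$base_temp_C) {
    rlang::abort("Constant temperature must exceed the base temperature for development to occur.")
  }
  threshold_for(dataset, stage) / (temp_C - dataset$base_temp_C)
}
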