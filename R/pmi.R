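#' Pre-colonization-interval rules
#'
#' A PCI rule states the minimum documented interval between death and first
#' insect colonization for a species within an ambient-temperature band.
#' The default table carries the published minimum for adult *Lucilia
#' sericata*: 0.2 day between 14.0 and 25.1 degrees C.
#'
#' @param species,temp_low_C,temp_high_C,min_pci_days,provenance Vectors
#'   defining one rule per element; omit all to get the default table.
#' @return Tibble with columns `species`, `temp_low_C`, `temp_high_C`,
#'   `min_pci_days`, `provenance`.
#' @export
pci_rules <- function(species = "Lucilia sericata",
                      temp_low_C = 14.0, temp_high_C = 25.1,
                      min_pci_days = 0.2,
                      provenance = "Matuszewski et al., minimum PCI for adult L. sericata") {
  out <- tibble::tibble(
    species = species, temp_low_C = temp_low_C, temp_high_C = temp_high_C,
    min_pci_days = min_pci_days, provenance = provenance
  )
  if (any(out$temp_low_C >= out$temp_high_C)) rlang::abort("PCI rule requires temp_low_C < temp_high_C.")
  if (any(out$min_pci_days < 0)) rlang::abort("min_pci_days must be non-negative.")
  out
}

#' Read PCI rules from YAML
#'
#' @param path YAML file with a top-level `rules:` list of
#'   `{species, temp_range_C: [low, high], min_pci_days, provenance}`.
#' @return Rules tibble as from [pci_rules()].
#' @export
read_pci_rules <- function(path) {
  y <- yaml::read_yaml(path)
  purrr::map_dfr(y$rules, function(r) {
    pci_rules(
      species = r$species,
      temp_low_C = r$temp_range_C[[1]], temp_high_C = r$temp_range_C[[2]],
      min_pci_days = r$min_pci_days,
      provenance = r$provenance %||% ""
    )
  })
}

#' Choose the reference species for back-calculation
#'
#' Among the species observed on the body, the reference is the one whose
#' development from oviposition to its observed oldest stage takes longest
#' at the prevailing mean temperature: as the slowest developer it must have
#' arrived earliest, so it gives the most conservative (earliest)
#' colonization bound. Ties break alphabetically.
#'
#' @param candidates Tibble `species, stage` from
#'   [oldest_stage_per_species()].
#' @param datasets Named list of `development_dataset` objects keyed by
#'   canonical species name.
#' @param mean_temp_C Mean scene temperature (°C) at which durations are
#'   compared.
#' @return Canonical species name of the reference taxon.
#' @export
select_reference_species <- function(candidates, datasets, mean_temp_C) {
  have <- candidates$species %in% names(datasets)
  if (!any(have)) {
    rlang::abort(paste0(
      "No development dataset available for any candidate species. Missing: ",
      paste(candidates$species, collapse = ", ")
    ))
  }
  if (!all(have)) {
    rlang::warn(paste0(
      "No development dataset for: ",
      paste(candidates$species[!have], collapse = ", "), "; excluded from reference selection."
    ))
  }
  scored <- candidates[have, , drop = FALSE] |>
    dplyr::mutate(
      duration_h = purrr::map2_dbl(
        .data$species, .data$stage,
        ~ duration_at_constant(datasets[[.x]], .y, mean_temp_C)
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$duration_h), .data$species)
  scored$species[1]
}

#' Estimate the minimum post-mortem interval for a case
#'
#' Full per-case orchestration: take the oldest observed stage per species,
#' choose the reference species, back-calculate oviposition time from the
#' collection time through the temperature record, and assemble the
#' stage-entry timeline, PMI-min and signed discrepancy against the case's
#' last-known-activity reference.
#'
#' @param case A `pmi_case`.
#' @param datasets Named list of `development_dataset` objects.
#' @param temps Either a scalar corrected mean scene temperature (°C) or an
#'   hourly `timestamp, temp_C` tibble covering the backward window. When an
#'   hourly series is supplied it wins over any scalar stored on the case.
#' @param pci Optional PCI rules tibble; when given, [apply_pci()] is run on
#'   the result.
#' @return Object of class `pmi_estimate`.
#' @export
estimate_pmi_min <- function(case, datasets, temps = NULL, pci = NULL) {
  if (nrow(case$specimens) == 0) {
    rlang::abort(paste0("Case ", case$case_id, ": specimen roster is empty."))
  }
  temps <- temps %||% case$corrected_mean_temp_C
  if (is.null(temps)) {
    rlang::abort(paste0(
      "Case ", case$case_id,
      ": no temperature input (corrected series or scalar mean) available."
    ))
  }
  at <- case$collection_time
  series_mode <- is.data.frame(temps)
  mean_temp <- if (series_mode) mean(temps$temp_C) else as.numeric(temps)

  oldest <- oldest_stage_per_species(case$specimens)
  ref_species <- withCallingHandlers(
    select_reference_species(oldest, datasets, mean_temp),
    error = function(e) {
      rlang::abort(paste0("Case ", case$case_id, ": ", conditionMessage(e)), parent = e)
    }
  )
  dataset <- datasets[[ref_species]]
  obs_stage <- as.character(oldest$stage[oldest$species == ref_species])

  series <- if (series_mode) {
    temps
  } else {
    dur <- duration_at_constant(dataset, obs_stage, mean_temp)
    constant_series(mean_temp, at - 3600 * (dur + 2), at)
  }
  bt <- backtrack_oviposition(dataset, series, obs_stage, at)
  disc <- discrepancy(bt$oviposition_time, case$last_known_activity,
    granularity = case$reference_granularity
  )
  est <- structure(
    list(
      case_id = case$case_id,
      reference_species = ref_species,
      observed_stage = obs_stage,
      oviposition_time = bt$oviposition_time,
      timeline = bt$timeline,
      pmi_min_hours = hours_between(bt$oviposition_time, at),
      collection_time = at,
      mean_temp_C = mean_temp,
      pci_applied_days = NA_real_,
      adjusted_bound_time = NULL,
      adjusted_gap_hours = NULL,
      discrepancy = disc,
      reference = case$last_known_activity,
      reference_granularity = case$reference_granularity,
      notes = case$notes
    ),
    class = "pmi_estimate"
  )
  if (!is.null(pci)) est <- apply_pci(est, pci) else est
}

#' Signed discrepancy between the entomological bound and a reference
#'
#' Minute-granularity references give the difference in hours; date-only
#' references give the difference in whole calendar days between the two
#' dates (clock time is ignored, as the reference carries none). Positive
#' values mean the entomological bound is later than the reference.
#'
#' @param pmi_min_time Estimated oviposition datetime (the PMI-min bound).
#' @param reference Reference timestamp: POSIXct/datetime string (minute
#'   granularity) or Date/"YYYY-MM-DD" (day granularity).
#' @param granularity `"minute"` or `"day"`; defaults from the class of
#'   `reference`.
#' @return One-row tibble `value, unit` (`unit` is `"hours"` or `"days"`).
#' @export
#' @examples
#' discrepancy("2022-05-14 15:00", "2022-05-13 16:00") # 23 hours
#' discrepancy("2022-08-09 03:50", as.Date("2022-08-07")) # 2 days
discrepancy <- function(pmi_min_time, reference, granularity = NULL) {
  pmi_min_time <- parse_local_dt(pmi_min_time)
  if (is.null(granularity)) {
    granularity <- if (inherits(reference, "Date") ||
      (is.character(reference) && !grepl("[ T]", reference))) {
      "day"
    } else {
      "minute"
    }
  }
  if (granularity == "day") {
    ref <- as.Date(substr(as.character(reference), 1, 10))
    tibble::tibble(
      value = as.numeric(as.Date(pmi_min_time, tz = "UTC") - ref),
      unit = "days"
    )
  } else {
    tibble::tibble(
      value = hours_between(parse_local_dt(reference), pmi_min_time),
      unit = "hours"
    )
  }
}

discrepancy_hours <- function(disc) {
  if (disc$unit == "days") disc$value * 24 else disc$value
}

#' Apply a pre-colonization-interval adjustment
#'
#' If a PCI rule matches the estimate's reference species and the mean scene
#' temperature falls inside the rule's band, the death-time bound is
#' extended earlier by the rule's minimum PCI and the residual gap against
#' the external reference shrinks by the same amount. With no matching rule
#' the estimate is returned unchanged (`pci_applied_days` stays `NA`).
#'
#' @param estimate A `pmi_estimate`.
#' @param rules PCI rules tibble, see [pci_rules()].
#' @param mean_temp_C Mean temperature to match against; defaults to the
#'   estimate's own mean.
#' @return The (possibly adjusted) `pmi_estimate`.
#' @export
apply_pci <- function(estimate, rules, mean_temp_C = NULL) {
  mean_temp_C <- mean_temp_C %||% estimate$mean_temp_C
  hit <- rules |>
    dplyr::filter(
      .data$species == estimate$reference_species,
      .data$temp_low_C <= mean_temp_C,
      mean_temp_C <= .data$temp_high_C
    )
  if (nrow(hit) > 1 && dplyr::n_distinct(hit$min_pci_days) > 1) {
    rlang::abort(paste0(
      "Conflicting overlapping PCI rules for ", estimate$reference_species,
      " at ", mean_temp_C, " °C."
    ))
  }
  if (nrow(hit) == 0) {
    return(estimate)
  }
  pci_days <- hit$min_pci_days[1]
  estimate$pci_applied_days <- pci_days
  estimate$adjusted_bound_time <- estimate$oviposition_time - pci_days * 86400
  estimate$adjusted_gap_hours <- discrepancy_hours(estimate$discrepancy) - pci_days * 24
  estimate
}

#' @export
print.pmi_estimate <- function(x, ...) {
  cat("<pmi_estimate> ", x$case_id, "\n", sep = "")
  cat("  reference species: ", x$reference_species, " (oldest stage: ", x$observed_stage, ")\n", sep = "")
  cat("  mean scene temperature: ", signif(x$mean_temp_C, 4), " °C\n", sep = "")
  cat("  oviposition (PMI-min bound): ", format_local_dt(x$oviposition_time), "\n", sep = "")
  cat("  PMI-min: ", round(x$pmi_min_hours, 1), " h before collection (",
    format_local_dt(x$collection_time), ")\n",
    sep = ""
  )
  cat("  discrepancy vs reference: ", x$discrepancy$value, " ", x$discrepancy$unit, "\n", sep = "")
  if (!is.na(x$pci_applied_days)) {
    cat("  PCI applied: ", x$pci_applied_days, " day(s); adjusted gap ",
      round(x$adjusted_gap_hours, 1), " h\n",
      sep = ""
    )
  } else {
    cat("  PCI: not applied\n")
  }
  invisible(x)
}

#' Tidy a PMI estimate into its stage timeline
#'
#' @param x A `pmi_estimate`.
#' @param ... Unused.
#' @return Tibble `stage, entry_time` (the back-calculated developmental
#'   timeline from oviposition to the observed stage).
#' @method tidy pmi_estimate
#' @export
tidy.pmi_estimate <- function(x, ...) {
  x$timeline
}

#' One-row summary of a PMI estimate
#'
#' @param x A `pmi_estimate`.
#' @param ... Unused.
#' @return Tibble with the case id, reference species, oviposition time,
#'   PMI-min hours, applied PCI, and the discrepancy value/unit.
#' @method glance pmi_estimate
#' @export
glance.pmi_estimate <- function(x, ...) {
  tibble::tibble(
    case_id = x$case_id,
    reference_species = x$reference_species,
    observed_stage = x$observed_stage,
    oviposition_time = x$oviposition_time,
    pmi_min_hours = x$pmi_min_hours,
    mean_temp_C = x$mean_temp_C,
    pci_applied_days = x$pci_applied_days,
    discrepancy_value = x$discrepancy$value,
    discrepancy_unit = x$discrepancy$unit
  )
}

#' Timeline plot of a PMI estimate
#'
#' Draws the back-calculated stage-entry timeline as horizontal segments
#' from each stage's entry to the next, with the oviposition bound and the
#' external reference marked.
#'
#' @param object A `pmi_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pmi_estimate
#' @export
autoplot.pmi_estimate <- function(object, ...) {
  tl <- object$timeline |>
    dplyr::mutate(
      stage = factor(.data$stage, levels = stage_levels()),
      exit_time = dplyr::lead(.data$entry_time, default = object$collection_time)
    )
  ref_time <- if (object$reference_granularity == "day") {
    as.POSIXct(paste(object$reference, "00:00"), tz = "UTC")
  } else {
    object$reference
  }
  ggplot2::ggplot(tl, ggplot2::aes(y = .data$stage)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$entry_time, xend = .data$exit_time, yend = .data$stage),
      linewidth = 3, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = as.numeric(object$oviposition_time), linetype = 2) +
    ggplot2::geom_vline(xintercept = as.numeric(ref_time), linetype = 3, colour = "firebrick") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste0(object$case_id, ": developmental timeline (", object$reference_species, ")"),
      subtitle = "dashed: estimated oviposition; dotted: last-known-activity reference"
    ) +
    ggplot2::theme_minimal()
}
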