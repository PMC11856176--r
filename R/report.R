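report_caveats <- function() {
  c(
    "PMI-min bounds colonization, not death: the pre-colonization interval adds unobserved time.",
    "Unquantified factors not modelled: nocturnal oviposition timing, maggot-mass heat, mixed broods, drugs/toxins.",
    "Interpretation of any PCI-adjusted gap assumes the published minimum PCI applies to this scene."
  )
}

fmt_dt_s <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

#' Write a PMI estimate report
#'
#' Writes a machine-readable JSON record of the estimate (timeline, PMI-min,
#' PCI adjustment, discrepancy) at `path`, plus a human-readable text report
#' alongside it (same name, `.txt`). The JSON round-trips losslessly through
#' [read_report()].
#'
#' @param estimate A `pmi_estimate`.
#' @param path Output path for the JSON record.
#' @return `estimate`, invisibly.
#' @export
write_report <- function(estimate, path) {
  x <- estimate
  payload <- list(
    case_id = x$case_id,
    reference_species = x$reference_species,
    observed_stage = x$observed_stage,
    oviposition_time = fmt_dt_s(x$oviposition_time),
    timeline = dplyr::mutate(x$timeline, entry_time = fmt_dt_s(.data$entry_time)),
    pmi_min_hours = x$pmi_min_hours,
    collection_time = fmt_dt_s(x$collection_time),
    mean_temp_C = x$mean_temp_C,
    pci_applied_days = if (is.na(x$pci_applied_days)) NULL else x$pci_applied_days,
    adjusted_bound_time = if (!is.null(x$adjusted_bound_time)) fmt_dt_s(x$adjusted_bound_time),
    adjusted_gap_hours = x$adjusted_gap_hours,
    discrepancy = list(value = x$discrepancy$value, unit = x$discrepancy$unit),
    reference = if (x$reference_granularity == "day") format(x$reference) else fmt_dt_s(x$reference),
    reference_granularity = x$reference_granularity,
    notes = x$notes,
    caveats = report_caveats()
  )
  tryCatch(
    # suppress the connection warning that precedes the error on bad paths
    suppressWarnings(
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    ),
    error = function(e) rlang::abort(paste0("Cannot write report to ", path, ": ", conditionMessage(e)))
  )
  txt_path <- paste0(sub("\\.json$", "", path), ".txt")
  lines <- c(
    paste0("PMI-min report - case ", x$case_id),
    strrep("=", 40),
    paste0("Reference species : ", x$reference_species, " (oldest stage ", x$observed_stage, ")"),
    paste0("Mean scene temp   : ", signif(x$mean_temp_C, 4), " degC"),
    paste0("Collection time   : ", format_local_dt(x$collection_time)),
    paste0("Oviposition bound : ", format_local_dt(x$oviposition_time)),
    paste0("PMI-min           : ", round(x$pmi_min_hours, 1), " h"),
    "",
    "Stage timeline (entry times):",
    paste0(
      "  ", format(x$timeline$stage, width = 12), " ",
      format_local_dt(x$timeline$entry_time)
    ),
    "",
    paste0(
      "Discrepancy vs reference (", payload$reference, ", ",
      x$reference_granularity, "): ", x$discrepancy$value, " ", x$discrepancy$unit
    ),
    if (is.na(x$pci_applied_days)) {
      "PCI adjustment    : not applied"
    } else {
      c(
        paste0("PCI adjustment    : ", x$pci_applied_days, " day(s)"),
        paste0("Adjusted bound    : ", format_local_dt(x$adjusted_bound_time)),
        paste0("Adjusted gap      : ", round(x$adjusted_gap_hours, 2), " h")
      )
    },
    "",
    "Caveats:",
    paste0("  - ", report_caveats())
  )
  writeLines(lines, txt_path)
  invisible(estimate)
}

#' Read a PMI estimate report
#'
#' @param path Path to a JSON record written by [write_report()].
#' @return The reconstructed `pmi_estimate`.
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      case_id = j$case_id,
      reference_species = j$reference_species,
      observed_stage = j$observed_stage,
      oviposition_time = parse_local_dt(j$oviposition_time),
      timeline = tibble::tibble(
        stage = j$timeline$stage,
        entry_time = parse_local_dt(j$timeline$entry_time)
      ),
      pmi_min_hours = j$pmi_min_hours,
      collection_time = parse_local_dt(j$collection_time),
      mean_temp_C = j$mean_temp_C,
      pci_applied_days = j$pci_applied_days %||% NA_real_,
      adjusted_bound_time = if (!is.null(j$adjusted_bound_time)) parse_local_dt(j$adjusted_bound_time),
      adjusted_gap_hours = j$adjusted_gap_hours,
      discrepancy = tibble::tibble(value = j$discrepancy$value, unit = j$discrepancy$unit),
      reference = if (j$reference_granularity == "day") as.Date(j$reference) else parse_local_dt(j$reference),
      reference_granularity = j$reference_granularity,
      notes = unlist(j$notes) %||% character()
    ),
    class = "pmi_estimate"
  )
}
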