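pmintr_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "pmintr")
  if (!nzchar(path)) rlang::abort(paste0("Packaged fixture not found: ", file.path(...)))
  path
}

#' The three Busan case fixtures
#'
#' Loads one of the three packaged 2022 Busan death-investigation cases:
#' the case record (timestamps, roster, last-known-activity reference,
#' corrected mean scene temperature) together with the case-calibrated
#' development datasets for the species on the body. The development laws
#' are synthetic stand-ins calibrated so that cumulative stage durations at
#' each case's corrected mean temperature reproduce the published
#' stage-boundary timestamps; cases 1 and 3 carry notes documenting
#' internal inconsistencies in their published timelines.
#'
#' @param n Case number, 1, 2 or 3.
#' @return List with `case` (a `pmi_case`), `datasets` (named list of
#'   `development_dataset`), and `mean_temp_C`.
#' @export
#' @examples
#' fx <- busan_case(2)
#' estimate_pmi_min(fx$case, fx$datasets)
busan_case <- function(n) {
  stopifnot(n %in% 1:3)
  case <- read_case(pmintr_extdata("cases", paste0("case", n, ".json")))
  files <- list.files(pmintr_extdata("development"),
    pattern = paste0("^case", n, "_.*\\.yaml$"), full.names = TRUE
  )
  datasets <- purrr::map(files, read_development_dataset)
  names(datasets) <- purrr::map_chr(datasets, "species")
  list(case = case, datasets = datasets, mean_temp_C = case$corrected_mean_temp_C)
}

#' Packaged molecular-identification table
#'
#' Path to the packaged TSV of COI identification results for all 24
#' specimens across the three Busan cases (sample IDs, sequence lengths,
#' species calls, GenBank accessions, identity percentages).
#'
#' @return File path, suitable for [parse_identification_table()].
#' @export
busan_identification_table <- function() {
  pmintr_extdata("identification_table.tsv")
}

#' Packaged PCI rules
#'
#' The default pre-colonization-interval rule set shipped with the package
#' (currently the published minimum for adult *Lucilia sericata*).
#'
#' @return PCI rules tibble, see [pci_rules()].
#' @export
busan_pci_rules <- function() {
  read_pci_rules(pmintr_extdata("pci_rules.yaml"))
}
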