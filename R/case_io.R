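#' Build a specimen roster
#'
#' Constructs and validates the tibble of insect specimens attached to a
#' case: one row per specimen with its molecular-identification annotations.
#'
#' @param sample_id Character sample identifiers.
#' @param species Species strings, normalized via [canonical_species()].
#' @param stage Developmental stage codes (see [stage_levels()]).
#' @param sequence_length_bp Optional positive integer COI sequence lengths.
#' @param accession Optional GenBank accession strings.
#' @param identity_pct Optional BLAST identity percentages in \[0, 100\].
#' @param registry Species registry, see [species_registry()].
#' @return Tibble of class `pmi_specimens` with columns `sample_id`,
#'   `species`, `stage` (ordered factor), `sequence_length_bp`, `accession`,
#'   `identity_pct`.
#' @export
specimens <- function(sample_id, species, stage,
                      sequence_length_bp = NA_integer_,
                      accession = NA_character_,
                      identity_pct = NA_real_,
                      registry = species_registry()) {
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    species = canonical_species(species, registry),
    stage = stage_factor(stage),
    sequence_length_bp = as.integer(sequence_length_bp),
    accession = as.character(accession),
    identity_pct = as.numeric(identity_pct)
  )
  bad_len <- !is.na(out$sequence_length_bp) & out$sequence_length_bp <= 0
  if (any(bad_len)) {
    rlang::abort("sequence_length_bp must be positive where present.")
  }
  bad_id <- !is.na(out$identity_pct) & (out$identity_pct < 0 | out$identity_pct > 100)
  if (any(bad_id)) {
    rlang::abort("identity_pct must lie in [0, 100] where present.")
  }
  class(out) <- c("pmi_specimens", class(out))
  out
}

#' Parse a molecular-identification table
#'
#' Reads a delimited text file of COI barcoding results (one row per
#' specimen: sample ID, sequence length, species call, GenBank accession,
#' identity percentage) into a validated specimen roster. Species strings are
#' normalized to canonical binomials via the registry.
#'
#' @param path Path to a TSV/CSV file with header
#'   `sample_id, sequence_length_bp, species, accession, identity_pct`.
#' @param registry Species registry, see [species_registry()].
#' @return A `pmi_specimens` tibble, one row per data row of the file.
#' @export
parse_identification_table <- function(path, registry = species_registry()) {
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE, strip.white = TRUE)
  names(raw) <- tolower(trimws(names(raw)))
  needed <- c("sample_id", "sequence_length_bp", "species", "accession", "identity_pct")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("Identification table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(specimens(character(), character(), character(), registry = registry))
  }
  len <- suppressWarnings(as.integer(raw$sequence_length_bp))
  idp <- suppressWarnings(as.numeric(raw$identity_pct))
  bad <- which(is.na(raw$sample_id) | raw$sample_id == "" |
    (!is.na(raw$sequence_length_bp) & raw$sequence_length_bp != "" & is.na(len)) |
    (!is.na(raw$identity_pct) & raw$identity_pct != "" & is.na(idp)))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Malformed identification-table row(s): ",
      paste(bad, collapse = ", "), " of ", path
    ))
  }
  # A "stage" column is optional in identification tables; default to egg so
  # the roster is structurally valid until stages are assigned from the
  # collection notes.
  stage <- if ("stage" %in% names(raw)) raw$stage else "egg"
  specimens(
    sample_id = raw$sample_id,
    species = raw$species,
    stage = stage,
    sequence_length_bp = len,
    accession = raw$accession,
    identity_pct = idp,
    registry = registry
  )
}

#' Count distinct species in a roster
#'
#' @param specimens A `pmi_specimens` tibble (or any tibble with a canonical
#'   `species` column).
#' @return Non-negative integer count of unique canonical species names.
#' @export
count_distinct_species <- function(specimens) {
  dplyr::n_distinct(specimens$species[!is.na(specimens$species)])
}

#' Oldest observed developmental stage per species
#'
#' For each species in the roster, returns the maximal stage under the fixed
#' ordering `egg < instar1 < instar2 < instar3 < post_feeding < puparium <
#' adult`. The oldest stage is the one driving the minimum post-mortem
#' interval: it bounds colonization time from below most tightly.
#'
#' @inheritParams count_distinct_species
#' @return Tibble with columns `species`, `stage` (ordered factor), one row
#'   per species, sorted by species name.
#' @export
oldest_stage_per_species <- function(specimens) {
  if (nrow(specimens) == 0) {
    rlang::abort("Specimen roster is empty; cannot determine oldest stages.")
  }
  specimens |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(stage = max(.data$stage), .groups = "drop") |>
    dplyr::arrange(.data$species)
}

#' Assemble a death-investigation case
#'
#' Bundles the timestamps, location class, specimen roster and
#' last-known-activity reference of one case. The reference's granularity is
#' explicit — a pharmacy receipt gives a minute, a phone-record date gives
#' only a day — and downstream discrepancy arithmetic honours it.
#'
#' @param case_id Case identifier string.
#' @param discovery_time Datetime the body was found (string or POSIXct).
#' @param collection_time Datetime the entomological evidence was secured;
#'   defaults to `discovery_time`. Must be no earlier than 24 h before
#'   discovery.
#' @param location_class `"indoor"` or `"outdoor"`.
#' @param specimens Specimen roster tibble, see [specimens()].
#' @param last_known_activity Reference timestamp: a datetime string for
#'   minute granularity, or a `"YYYY-MM-DD"` date string with
#'   `reference_granularity = "day"`.
#' @param reference_granularity `"minute"` or `"day"`; never inferred.
#' @param corrected_mean_temp_C Optional scalar corrected scene mean (°C).
#' @param notes Optional character annotations carried into reports.
#' @return Object of class `pmi_case`.
#' @export
pmi_case <- function(case_id, discovery_time, collection_time = NULL,
                     location_class = c("indoor", "outdoor"),
                     specimens,
                     last_known_activity,
                     reference_granularity = c("minute", "day"),
                     corrected_mean_temp_C = NULL,
                     notes = character()) {
  location_class <- match.arg(location_class)
  reference_granularity <- match.arg(reference_granularity)
  discovery_time <- parse_local_dt(discovery_time)
  collection_time <- if (is.null(collection_time)) discovery_time else parse_local_dt(collection_time)
  if (hours_between(discovery_time, collection_time) < -24) {
    rlang::abort("collection_time must be no earlier than 24 h before discovery_time.")
  }
  ref <- if (reference_granularity == "day") {
    as.Date(substr(as.character(last_known_activity), 1, 10))
  } else {
    parse_local_dt(last_known_activity)
  }
  structure(
    list(
      case_id = as.character(case_id),
      discovery_time = discovery_time,
      collection_time = collection_time,
      location_class = location_class,
      specimens = specimens,
      last_known_activity = ref,
      reference_granularity = reference_granularity,
      corrected_mean_temp_C = corrected_mean_temp_C,
      notes = notes
    ),
    class = "pmi_case"
  )
}

#' @export
print.pmi_case <- function(x, ...) {
  cat("<pmi_case> ", x$case_id, " (", x$location_class, ")\n", sep = "")
  cat("  discovery:  ", format_local_dt(x$discovery_time), "\n", sep = "")
  cat("  collection: ", format_local_dt(x$collection_time), "\n", sep = "")
  cat("  reference:  ",
    if (x$reference_granularity == "day") format(x$last_known_activity) else format_local_dt(x$last_known_activity),
    " (", x$reference_granularity, ")\n",
    sep = ""
  )
  if (!is.null(x$corrected_mean_temp_C)) {
    cat("  corrected mean temp: ", x$corrected_mean_temp_C, " °C\n", sep = "")
  }
  cat("  specimens: ", nrow(x$specimens), " (", count_distinct_species(x$specimens),
    " species)\n",
    sep = ""
  )
  invisible(x)
}

#' Write a case to JSON
#'
#' @param case A `pmi_case` object.
#' @param path Output path.
#' @return `case`, invisibly.
#' @export
write_case <- function(case, path) {
  spec <- case$specimens
  payload <- list(
    case_id = case$case_id,
    discovery_time = format_local_dt(case$discovery_time),
    collection_time = format_local_dt(case$collection_time),
    location_class = case$location_class,
    specimens = dplyr::mutate(tibble::as_tibble(spec), stage = as.character(.data$stage)),
    last_known_activity = if (case$reference_granularity == "day") {
      format(case$last_known_activity)
    } else {
      format_local_dt(case$last_known_activity)
    },
    reference_granularity = case$reference_granularity,
    corrected_mean_temp_C = case$corrected_mean_temp_C,
    notes = case$notes
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(case)
}

#' Read a case from JSON
#'
#' @param path Path to a case JSON file written by [write_case()] (or
#'   hand-authored to the same schema).
#' @param registry Species registry for roster normalization.
#' @return A `pmi_case` object.
#' @export
read_case <- function(path, registry = species_registry()) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- j$specimens
  roster <- specimens(
    sample_id = sp$sample_id,
    species = sp$species,
    stage = sp$stage,
    sequence_length_bp = if ("sequence_length_bp" %in% names(sp)) sp$sequence_length_bp else NA,
    accession = if ("accession" %in% names(sp)) sp$accession else NA,
    identity_pct = if ("identity_pct" %in% names(sp)) sp$identity_pct else NA,
    registry = registry
  )
  pmi_case(
    case_id = j$case_id,
    discovery_time = j$discovery_time,
    collection_time = j$collection_time,
    location_class = j$location_class,
    specimens = roster,
    last_known_activity = j$last_known_activity,
    reference_granularity = j$reference_granularity,
    corrected_mean_temp_C = j$corrected_mean_temp_C,
    notes = unlist(j$notes) %||% character()
  )
}
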