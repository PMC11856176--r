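#' Blowfly developmental stages, in order
#'
#' The fixed total ordering of immature-to-adult stages used throughout the
#' package: `egg < instar1 < instar2 < instar3 < post_feeding < puparium <
#' adult`. Stage comparisons ("oldest observed stage") and ADH thresholds are
#' defined against this ordering.
#'
#' @return Character vector of the seven stage codes, youngest first.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() {
  c("egg", "instar1", "instar2", "instar3", "post_feeding", "puparium", "adult")
}

#' Coerce stage codes to an ordered factor
#'
#' @param x Character vector of stage codes (see [stage_levels()]).
#' @return Ordered factor over the seven stages.
#' @export
stage_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(stage_levels(), NA))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Unknown stage code(s): ", paste(bad, collapse = ", "),
      ". Accepted stages: ", paste(stage_levels(), collapse = " < ")
    ))
  }
  factor(as.character(x), levels = stage_levels(), ordered = TRUE)
}

#' Species registry for necrophagous taxa
#'
#' An extensible table mapping raw species strings (abbreviated binomials,
#' synonyms, italic-markup leftovers) to canonical binomials. The default
#' registry covers the two urban first colonizers handled by the shipped case
#' fixtures; supply additional rows to register further taxa without code
#' changes.
#'
#' @param extra Optional tibble with columns `species` (canonical binomial)
#'   and `synonyms` (list-column of character vectors) appended to the
#'   defaults.
#' @return Tibble with columns `species`, `synonyms`.
#' @export
#' @examples
#' species_registry()
species_registry <- function(extra = NULL) {
  reg <- tibble::tibble(
    species = c("Lucilia sericata", "Chrysomya megacephala"),
    synonyms = list(
      c("L. sericata", "L.sericata", "Lucilia sericata (Meigen)"),
      c("C. megacephala", "C.megacephala", "Chrysomya megacephala (Fabricius)")
    )
  )
  if (!is.null(extra)) {
    stopifnot(all(c("species", "synonyms") %in% names(extra)))
    reg <- dplyr::bind_rows(reg, tibble::as_tibble(extra))
  }
  reg
}

#' Normalize species strings to canonical binomials
#'
#' Strips markdown/italic markup and whitespace, then resolves each string
#' against the registry (canonical names and synonyms, case-insensitive).
#'
#' @param x Character vector of raw species strings.
#' @param registry Registry tibble from [species_registry()].
#' @return Character vector of canonical binomials.
#' @export
canonical_species <- function(x, registry = species_registry()) {
  clean <- gsub("[*_]", "", as.character(x))
  clean <- gsub("\\s+", " ", trimws(clean))
  lut <- registry |>
    dplyr::mutate(alias = purrr::map2(.data$species, .data$synonyms, ~ c(.x, .y))) |>
    dplyr::select("species", "alias") |>
    tidyr::unnest("alias")
  idx <- match(tolower(clean), tolower(lut$alias))
  out <- lut$species[idx]
  if (anyNA(out[!is.na(clean)])) {
    bad <- unique(clean[is.na(out) & !is.na(clean)])
    rlang::abort(paste0(
      "Unknown species name(s): ", paste(bad, collapse = "; "),
      ". Accepted taxa: ", paste(registry$species, collapse = ", "),
      " (extend via species_registry(extra = ...))."
    ))
  }
  out
}

# Parse "2022-08-12 14:50" / ISO-8601 "2022-08-12T14:50:00" as a
# timezone-naive local datetime (represented in UTC; no DST logic).
parse_local_dt <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- gsub("T", " ", as.character(x))
  out <- as.POSIXct(x,
    tz = "UTC",
    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  )
  if (anyNA(out) && !anyNA(x)) {
    rlang::abort(paste0("Unparseable datetime(s): ", paste(x[is.na(out)], collapse = ", ")))
  }
  out
}

format_local_dt <- function(x) format(x, "%Y-%m-%d %H:%M", tz = "UTC")

hours_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}
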