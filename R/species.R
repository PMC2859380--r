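#' Species registry
#'
#' A species registry declares the organisms taking part in one analysis: a
#' short species code used in the input tables, the single uppercase genus
#' letter used in SpeciesNotation strings, a display name, and the NCBI
#' taxonomy identifier used to filter interaction rows. Genus letters must be
#' unique within one registry because SpeciesNotation encodes one letter per
#' species.
#'
#' The default registry holds the five organisms the method was designed
#' around: human, mouse, fly, worm and budding yeast (letters H, M, D, C, S).
#' The order of registry rows fixes the letter order of SpeciesNotation.
#'
#' @return A tibble with columns `code`, `genus_letter`, `name`, `taxid`.
#' @examples
#' default_species_registry()
#' @export
default_species_registry <- function() {
  tibble(
    code = c("hsap", "mmus", "dmel", "cele", "scer"),
    genus_letter = c("H", "M", "D", "C", "S"),
    name = c(
      "Homo sapiens", "Mus musculus", "Drosophila melanogaster",
      "Caenorhabditis elegans", "Saccharomyces cerevisiae"
    ),
    taxid = c(9606L, 10090L, 7227L, 6239L, 4932L)
  )
}

validate_registry <- function(registry) {
  assert_columns(registry, c("code", "genus_letter"), "species registry")
  if (!"taxid" %in% names(registry)) registry$taxid <- NA_integer_
  if (!"name" %in% names(registry)) registry$name <- registry$code
  if (anyDuplicated(registry$code) > 0) {
    stop("species registry has duplicate species codes", call. = FALSE)
  }
  if (anyDuplicated(registry$genus_letter) > 0) {
    stop("genus letters must be unique within a registry", call. = FALSE)
  }
  if (any(!nzchar(registry$code))) {
    stop("species codes must be non-empty", call. = FALSE)
  }
  as_tibble(registry[, c("code", "genus_letter", "name", "taxid")])
}

#' Read or write a species registry
#'
#' Registries are stored as YAML or JSON (chosen by file extension): a list of
#' records with fields `code`, `genus_letter`, `name`, `taxid`.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_species_registry()` returns a validated registry tibble;
#'   `write_species_registry()` returns `path` invisibly.
#' @export
read_species_registry <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    dplyr::bind_rows(lapply(yaml::read_yaml(path), as_tibble))
  }
  recs <- as_tibble(recs)
  if ("taxid" %in% names(recs)) recs$taxid <- as.integer(recs$taxid)
  validate_registry(recs)
}

#' @rdname read_species_registry
#' @param registry A species registry tibble.
#' @export
write_species_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(registry, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(
      lapply(seq_len(nrow(registry)), function(i) as.list(registry[i, ])),
      path
    )
  }
  invisible(path)
}
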