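#' Read a cross-species orthology table
#'
#' The orthology dialect is a UTF-8, tab-separated table with a header row and
#' the six columns `source_gene`, `source_species`, `target_gene`,
#' `target_species`, `homology_type`, `percent_identity`. Each row is one
#' directed orthologue record: `percent_identity` is the percentage of the
#' *source* protein's residues identical to the target orthologue, so the
#' reciprocal record (target species' perspective) carries its own value.
#' `homology_type` is one of `one2one`, `one2many`, `many2many`.
#'
#' Rows are validated, not trusted: rows naming a species absent from the
#' registry, with identity outside \[0, 100\], with an unknown homology type,
#' or relating a gene to its own species are rejected and counted; exact
#' duplicate (source gene, target gene, species pair) records are dropped.
#' Rejection counts are attached as the `"rejections"` attribute (see
#' [rejection_report()]) and reported with a message.
#'
#' @param path Path to the orthology TSV.
#' @param registry Species registry tibble (see [default_species_registry()]).
#' @return A tibble of validated orthologue records (the orthology map).
#' @seealso [orthologues_of()], [write_orthology()]
#' @export
read_orthology <- function(path, registry = default_species_registry()) {
  registry <- validate_registry(registry)
  cols <- c(
    "source_gene", "source_species", "target_gene", "target_species",
    "homology_type", "percent_identity"
  )
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  assert_columns(raw, cols, "orthology table")
  raw <- raw[, cols]
  raw$percent_identity <- suppressWarnings(as.numeric(raw$percent_identity))

  known_species <- registry$code
  bad_species <- !(raw$source_species %in% known_species &
    raw$target_species %in% known_species)
  bad_identity <- is.na(raw$percent_identity) |
    raw$percent_identity < 0 | raw$percent_identity > 100
  bad_type <- !raw$homology_type %in% c("one2one", "one2many", "many2many")
  self_species <- raw$source_species == raw$target_species
  keep <- !(bad_species | bad_identity | bad_type | self_species)

  out <- raw[keep, ]
  dup <- duplicated(out[, c(
    "source_gene", "target_gene",
    "source_species", "target_species"
  )])
  rejections <- c(
    unknown_species = sum(bad_species),
    identity_out_of_range = sum(bad_identity & !bad_species),
    bad_homology_type = sum(bad_type & !bad_species & !bad_identity),
    self_species = sum(self_species & keep == FALSE &
      !bad_species & !bad_identity & !bad_type),
    duplicate = sum(dup)
  )
  out <- out[!dup, ]
  if (sum(rejections) > 0) {
    message(sprintf(
      "read_orthology: rejected %d row(s) (%s)",
      sum(rejections),
      paste(names(rejections)[rejections > 0], rejections[rejections > 0],
        sep = "=", collapse = ", "
      )
    ))
  }
  if (nrow(out) == 0 && nrow(raw) == 0) {
    warning("empty orthology file: returning an empty map", call. = FALSE)
  }
  structure(as_tibble(out), rejections = rejections)
}

empty_orthology <- function() {
  tibble(
    source_gene = character(), source_species = character(),
    target_gene = character(), target_species = character(),
    homology_type = character(), percent_identity = double()
  )
}

#' Write an orthology table in canonical form
#'
#' Records are sorted by all columns before writing so that equal maps yield
#' byte-identical files; `write_orthology(read_orthology(f), f2)` reproduces
#' `f` up to canonical row order.
#'
#' @param ortho An orthology map tibble.
#' @param path Output TSV path.
#' @export
write_orthology <- function(ortho, path) {
  ortho <- dplyr::arrange(
    ortho, .data$source_species, .data$target_species,
    .data$source_gene, .data$target_gene
  )
  readr::write_tsv(ortho, path, progress = FALSE)
  invisible(path)
}

#' Look up the orthologues of a gene in a target species
#'
#' Returns all orthologue records of `gene` toward `target_species`, sorted by
#' descending percent identity (the order in which they contribute to an
#' OrthoScore). A gene with no orthologues yields an empty tibble, never an
#' error.
#'
#' @param ortho An orthology map tibble.
#' @param gene A source gene identifier.
#' @param target_species Target species code.
#' @return A tibble of matching orthologue records.
#' @export
orthologues_of <- function(ortho, gene, target_species) {
  out <- ortho[ortho$source_gene == gene &
    ortho$target_species == target_species, ]
  out[order(-out$percent_identity), ]
}

#' Read an identifier synonym table
#'
#' Tab-separated with header and columns `external_id`, `gene_id`, `species`,
#' `status`. `status` is `known` or `novel` for current identifiers; `retired`
#' marks an external identifier whose replacement current identifier is given
#' in `gene_id`. Retired rows without a replacement are dropped (with a
#' message); an external identifier may map to at most one current gene.
#'
#' @param path Path to the synonym TSV.
#' @return A tibble synonym table.
#' @export
read_synonyms <- function(path) {
  syn <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  assert_columns(syn, c("external_id", "gene_id", "species", "status"),
    what = "synonym table"
  )
  no_repl <- syn$status == "retired" & (is.na(syn$gene_id) | !nzchar(syn$gene_id))
  if (any(no_repl)) {
    message(sprintf(
      "read_synonyms: dropped %d retired id(s) without replacement",
      sum(no_repl)
    ))
    syn <- syn[!no_repl, ]
  }
  dup <- duplicated(syn$external_id)
  if (any(dup)) {
    message(sprintf(
      "read_synonyms: dropped %d duplicate external id(s)", sum(dup)
    ))
    syn <- syn[!dup, ]
  }
  as_tibble(syn)
}

#' Normalize interactor identifiers against a synonym table
#'
#' Maps both interactor columns of raw interaction rows to current gene
#' identifiers: retired accessions are mapped forward to their replacement,
#' synonyms are converted, and rows whose mapped gene belongs to a species
#' other than `expected_species` (or that cannot be mapped at all) are
#' dropped. Nothing here is fatal; all outcomes are counted in the rejection
#' report attached as the `"report"` attribute (see [rejection_report()]).
#' The operation is idempotent: normalized rows pass through unchanged.
#'
#' @param raw_edges Tibble of raw interaction rows with columns
#'   `interactor_a`, `interactor_b` (other columns are preserved).
#' @param synonyms Synonym table from [read_synonyms()].
#' @param expected_species Species code the rows are expected to belong to.
#' @param keep_novel Keep genes whose status is `novel` (default TRUE);
#'   when FALSE they are dropped and counted as `dropped_novel`.
#' @return Tibble of normalized rows with a `"report"` attribute holding
#'   counts `converted`, `dropped_species_mismatch`, `dropped_unmappable`,
#'   `dropped_novel`.
#' @export
normalize_identifiers <- function(raw_edges, synonyms, expected_species,
                                  keep_novel = TRUE) {
  assert_columns(raw_edges, c("interactor_a", "interactor_b"), "raw edges")

  # current-id view: a gene_id maps to itself (status of its own record)
  current <- synonyms[synonyms$status != "retired", ]
  self_map <- dplyr::distinct(
    tibble(
      external_id = current$gene_id, gene_id = current$gene_id,
      species = current$species, status = current$status
    ),
    .data$external_id,
    .keep_all = TRUE
  )
  lookup <- dplyr::bind_rows(
    synonyms[, c("external_id", "gene_id", "species", "status")],
    dplyr::anti_join(self_map, synonyms, by = "external_id")
  )

  # status and species of the RESULT gene (a retired id's replacement
  # carries its replacement's status, not "retired")
  gene_species <- setNames(self_map$species, self_map$external_id)
  gene_status <- setNames(self_map$status, self_map$external_id)
  resolve <- function(ids) {
    i <- match(ids, lookup$external_id)
    mapped <- lookup$gene_id[i]
    tibble(
      mapped = mapped,
      species = unname(ifelse(
        mapped %in% names(gene_species),
        gene_species[mapped], lookup$species[i]
      )),
      status = unname(ifelse(
        mapped %in% names(gene_status),
        gene_status[mapped], lookup$status[i]
      )),
      changed = !is.na(i) & mapped != ids
    )
  }
  ra <- resolve(raw_edges$interactor_a)
  rb <- resolve(raw_edges$interactor_b)

  unmappable <- is.na(ra$mapped) | is.na(rb$mapped)
  mismatch <- !unmappable &
    (ra$species != expected_species | rb$species != expected_species)
  novel <- !unmappable & !mismatch &
    (ra$status == "novel" | rb$status == "novel")
  drop_novel <- if (keep_novel) rep(FALSE, nrow(raw_edges)) else novel
  keep <- !(unmappable | mismatch | drop_novel)

  out <- raw_edges[keep, ]
  out$interactor_a <- ra$mapped[keep]
  out$interactor_b <- rb$mapped[keep]
  report <- c(
    converted = sum((ra$changed + rb$changed)[keep]),
    dropped_species_mismatch = sum(mismatch),
    dropped_unmappable = sum(unmappable),
    dropped_novel = sum(drop_novel)
  )
  structure(as_tibble(out), report = report)
}

#' Rejection/conversion report of a loader
#'
#' Loaders and normalizers in this package never fail on bad rows; they count
#' them. This accessor returns those counts (a named integer vector), or
#' `NULL` when the object carries none.
#'
#' @param x An object returned by [read_orthology()] or
#'   [normalize_identifiers()].
#' @export
rejection_report <- function(x) {
  attr(x, "report", exact = TRUE) %||% attr(x, "rejections", exact = TRUE)
}
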