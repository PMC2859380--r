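#' Read one database's binary protein-protein interaction file
#'
#' The PPI dialect is tab-separated with a header and columns `interactor_a`,
#' `interactor_b`, `taxid_a`, `taxid_b`, `experiment_type`, `evidence_id`,
#' `source_db`. Files in the BIND-style dialect lack the experiment columns;
#' their rows receive the sentinel experiment type `"protein_protein"` and a
#' row-derived evidence identifier, so an interaction annotated only by such
#' a source later scores ExperimentScore 1.
#'
#' Two filters are applied, with counts attached as the `"report"` attribute:
#' rows whose two taxon identifiers are not both the declared species are
#' dropped (cross-species and mis-annotated rows), and rows flagged as
#' involving a non-protein molecule (optional columns `molecule_type_a`/`_b`,
#' kept when equal to `"protein"`) are dropped.
#'
#' @param path Path to the PPI TSV.
#' @param db_name Name of the source database (used when the file has no
#'   `source_db` column and to derive sentinel evidence ids).
#' @param species Species code the file is declared to contain.
#' @param registry Species registry supplying the species' taxon id.
#' @return Tibble of raw interaction rows: `interactor_a`, `interactor_b`,
#'   `species`, `experiment_type`, `evidence_id`, `source_db`.
#' @export
read_ppi <- function(path, db_name, species,
                     registry = default_species_registry()) {
  registry <- validate_registry(registry)
  if (!species %in% registry$code) {
    stop(sprintf("species '%s' is not in the registry", species), call. = FALSE)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  assert_columns(raw, c("interactor_a", "interactor_b", "taxid_a", "taxid_b"),
    what = sprintf("PPI table '%s'", db_name)
  )
  if (!"experiment_type" %in% names(raw)) {
    # BIND-style dialect: no experiment annotation
    raw$experiment_type <- "protein_protein"
    raw$evidence_id <- paste0(db_name, ":row", seq_len(nrow(raw)))
  }
  if (!"evidence_id" %in% names(raw)) {
    raw$evidence_id <- paste0(db_name, ":row", seq_len(nrow(raw)))
  }
  if (!"source_db" %in% names(raw)) raw$source_db <- db_name

  taxid <- registry$taxid[registry$code == species]
  tax_ok <- !is.na(raw$taxid_a) & !is.na(raw$taxid_b) &
    as.integer(raw$taxid_a) == taxid & as.integer(raw$taxid_b) == taxid

  protein_ok <- rep(TRUE, nrow(raw))
  for (col in c("molecule_type_a", "molecule_type_b")) {
    if (col %in% names(raw)) protein_ok <- protein_ok & raw[[col]] == "protein"
  }

  keep <- tax_ok & protein_ok
  out <- tibble(
    interactor_a = raw$interactor_a[keep],
    interactor_b = raw$interactor_b[keep],
    species = species,
    experiment_type = raw$experiment_type[keep],
    evidence_id = raw$evidence_id[keep],
    source_db = raw$source_db[keep]
  )
  report <- c(
    dropped_taxon_mismatch = sum(!tax_ok),
    dropped_non_protein = sum(tax_ok & !protein_ok)
  )
  if (sum(report) > 0) {
    message(sprintf(
      "read_ppi(%s): dropped %d row(s) (taxon mismatch %d, non-protein %d)",
      db_name, sum(report), report[[1]], report[[2]]
    ))
  }
  structure(out, report = report)
}

#' Merge per-database interaction rows into a non-redundant interactome
#'
#' Combines normalized rows from any number of database files into one
#' interactome per species: one interaction per unordered gene pair
#' (canonically sorted, so (A,B) and (B,A) collapse), with an evidence set in
#' which each distinct (experiment type, evidence id) pair is kept exactly
#' once regardless of how many databases reported it. Self-interactions
#' (A,A) are retained and flagged in the `self` column; topology metrics
#' ignore them. The merge is order-invariant: permuting the input rows or
#' database order yields an identical interactome.
#'
#' @param rows A tibble of interaction rows (as from [read_ppi()], possibly
#'   after [normalize_identifiers()]), or a list of such tibbles.
#' @return A nested tibble (one row per interaction): `species`, `gene_a`,
#'   `gene_b`, `origin` (`"known"`), `self`, `n_evidence`, and list-column
#'   `evidence` of tibbles with `experiment_type`, `evidence_id`, `source_db`.
#' @export
merge_interactomes <- function(rows) {
  if (is.data.frame(rows)) rows <- list(rows)
  rows <- lapply(rows, function(r) {
    if ("interactor_a" %in% names(r)) {
      r <- dplyr::rename(r,
        gene_a = "interactor_a", gene_b = "interactor_b"
      )
    }
    r
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0) {
    return(tibble(
      species = character(), gene_a = character(), gene_b = character(),
      origin = character(), self = logical(), n_evidence = integer(),
      evidence = list()
    ))
  }
  assert_columns(
    rows,
    c("gene_a", "gene_b", "species", "experiment_type", "evidence_id"),
    "interaction rows"
  )
  if (!"source_db" %in% names(rows)) rows$source_db <- NA_character_

  rows <- canonicalize_pairs(rows)
  rows |>
    dplyr::group_by(.data$species, .data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      evidence = list(
        dplyr::arrange(
          dplyr::summarise(
            dplyr::group_by(
              dplyr::pick("experiment_type", "evidence_id", "source_db"),
              .data$experiment_type, .data$evidence_id
            ),
            source_db = paste(sort(unique(.data$source_db)), collapse = ","),
            .groups = "drop"
          ),
          .data$experiment_type, .data$evidence_id
        )
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      origin = "known",
      self = .data$gene_a == .data$gene_b,
      n_evidence = vapply(.data$evidence, nrow, integer(1))
    ) |>
    dplyr::arrange(.data$species, .data$gene_a, .data$gene_b) |>
    dplyr::select(
      "species", "gene_a", "gene_b", "origin", "self",
      "n_evidence", "evidence"
    )
}

#' Gene and interaction overlap between source databases
#'
#' Pure counting over canonical pairs: how many genes and distinct
#' interactions each database contributes, and how many are shared between
#' each pair of databases (and by all databases together).
#'
#' @param rows Interaction rows carrying a `source_db` column (a tibble or a
#'   list of tibbles as accepted by [merge_interactomes()]).
#' @return A list with tibbles `per_db` (database, n_genes, n_interactions),
#'   `pairwise` (db_x, db_y, shared_genes, shared_interactions) and scalars
#'   `union_interactions`, `shared_all`.
#' @export
overlap_stats <- function(rows) {
  if (is.data.frame(rows)) rows <- list(rows)
  rows <- dplyr::bind_rows(rows)
  if ("interactor_a" %in% names(rows)) {
    rows <- dplyr::rename(rows, gene_a = "interactor_a", gene_b = "interactor_b")
  }
  assert_columns(rows, c("gene_a", "gene_b", "source_db"), "interaction rows")
  rows <- canonicalize_pairs(rows)
  rows$key <- pair_key(rows$gene_a, rows$gene_b)

  dbs <- sort(unique(rows$source_db))
  genes_by_db <- lapply(dbs, function(d) {
    unique(c(rows$gene_a[rows$source_db == d], rows$gene_b[rows$source_db == d]))
  })
  pairs_by_db <- lapply(dbs, function(d) unique(rows$key[rows$source_db == d]))
  names(genes_by_db) <- names(pairs_by_db) <- dbs

  per_db <- tibble(
    database = dbs,
    n_genes = vapply(genes_by_db, length, integer(1)),
    n_interactions = vapply(pairs_by_db, length, integer(1))
  )
  pw <- tidyr::expand_grid(db_x = dbs, db_y = dbs) |>
    dplyr::filter(.data$db_x < .data$db_y)
  pw$shared_genes <- mapply(
    function(x, y) length(intersect(genes_by_db[[x]], genes_by_db[[y]])),
    pw$db_x, pw$db_y,
    USE.NAMES = FALSE
  )
  pw$shared_interactions <- mapply(
    function(x, y) length(intersect(pairs_by_db[[x]], pairs_by_db[[y]])),
    pw$db_x, pw$db_y,
    USE.NAMES = FALSE
  )
  list(
    per_db = per_db,
    pairwise = pw,
    union_interactions = length(unique(rows$key)),
    shared_all = length(Reduce(intersect, pairs_by_db))
  )
}

#' Read/write a merged interactome as TSV
#'
#' One row per interaction: `species`, `gene_a`, `gene_b`, `origin` and the
#' evidence set serialized as `experiment_type;evidence_id;source_db` records
#' joined with `|`. Writing is deterministic (canonical sort).
#'
#' @param interactome A merged interactome tibble ([merge_interactomes()]).
#' @param path Output/input TSV path.
#' @export
write_interactome <- function(interactome, path) {
  flat <- interactome |>
    dplyr::arrange(.data$species, .data$gene_a, .data$gene_b) |>
    dplyr::mutate(evidence = vapply(
      .data$evidence,
      function(ev) {
        blank <- function(x) ifelse(is.na(x), "", x)
        paste(
          paste(blank(ev$experiment_type), blank(ev$evidence_id),
            blank(ev$source_db),
            sep = ";"
          ),
          collapse = "|"
        )
      },
      character(1)
    )) |>
    dplyr::select("species", "gene_a", "gene_b", "origin", "evidence")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_interactome
#' @export
read_interactome <- function(path) {
  flat <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  assert_columns(flat, c("species", "gene_a", "gene_b", "origin", "evidence"),
    what = "interactome table"
  )
  flat |>
    dplyr::mutate(
      evidence = lapply(strsplit(.data$evidence, "|", fixed = TRUE), function(recs) {
        parts <- strsplit(recs, ";", fixed = TRUE)
        unblank <- function(x) {
          x[is.na(x) | !nzchar(x)] <- NA_character_
          x
        }
        tibble(
          experiment_type = unblank(vapply(parts, `[`, character(1), 1)),
          evidence_id = unblank(vapply(parts, `[`, character(1), 2)),
          source_db = unblank(vapply(parts, `[`, character(1), 3))
        )
      }),
      self = .data$gene_a == .data$gene_b,
      n_evidence = vapply(.data$evidence, nrow, integer(1))
    ) |>
    dplyr::select(
      "species", "gene_a", "gene_b", "origin", "self",
      "n_evidence", "evidence"
    )
}
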