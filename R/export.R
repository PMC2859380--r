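#' Write a scored network in Cytoscape-compatible files
#'
#' Emits, per species, a SIF file (`geneA <tab> relation <tab> geneB`, with
#' relation `pp` for known and `pred` for predicted edges by default), one
#' edge-attribute `.eda` file per score (`geneA (relation) geneB = value`,
#' scores at 3 decimals) plus SpeciesNotation and orthology-type attribute
#' files, and a single modern edge-attribute TSV combining everything.
#' Output is deterministic: canonical pair order, sorted emission, fixed
#' decimal formatting.
#'
#' @param scored Scored interactions from [score_interactions()].
#' @param outdir Output directory (created if needed).
#' @param ortho Optional orthology map used to annotate each edge's
#'   orthology type (the types linking the two partners to their supporting
#'   species); omitted edges get `-`.
#' @param relations Length-2 named character vector mapping origins to SIF
#'   relation tokens (default `c(known = "pp", predicted = "pred")`).
#' @return Named list of written file paths, invisibly.
#' @export
write_cytoscape <- function(scored, outdir, ortho = NULL,
                            relations = c(known = "pp", predicted = "pred")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (sp in sort(unique(scored$species))) {
    rows <- scored[scored$species == sp, ] |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
    rel <- unname(relations[rows$origin])
    p <- function(ext) file.path(outdir, paste0(sp, ext))

    writeLines(
      paste(rows$gene_a, rel, rows$gene_b, sep = "\t"),
      p(".sif")
    )
    paths[[paste0(sp, ".sif")]] <- p(".sif")

    edge_name <- sprintf("%s (%s) %s", rows$gene_a, rel, rows$gene_b)
    eda <- function(file, values, header) {
      writeLines(c(header, sprintf("%s = %s", edge_name, values)), file)
      file
    }
    paths[[paste0(sp, ".interoscore.eda")]] <- eda(
      p(".interoscore.eda"), format_score(rows$intero_score), "InteroScore"
    )
    paths[[paste0(sp, ".speciesscore.eda")]] <- eda(
      p(".speciesscore.eda"), format_score(rows$species_score), "SpeciesScore"
    )
    paths[[paste0(sp, ".experimentscore.eda")]] <- eda(
      p(".experimentscore.eda"), rows$experiment_score, "ExperimentScore"
    )
    paths[[paste0(sp, ".speciesnotation.eda")]] <- eda(
      p(".speciesnotation.eda"), rows$species_notation, "SpeciesNotation"
    )
    ortho_type <- edge_orthology_type(rows, ortho)
    paths[[paste0(sp, ".orthotype.eda")]] <- eda(
      p(".orthotype.eda"), ortho_type, "OrthologyType"
    )

    tsv <- tibble(
      gene_a = rows$gene_a, relation = rel, gene_b = rows$gene_b,
      origin = rows$origin,
      intero_score = format_score(rows$intero_score),
      species_score = format_score(rows$species_score),
      experiment_score = rows$experiment_score,
      experiment_quality_score = format_score(rows$experiment_quality_score),
      species_notation = rows$species_notation,
      orthology_type = ortho_type
    )
    readr::write_tsv(tsv, p(".edges.tsv"), progress = FALSE)
    paths[[paste0(sp, ".edges.tsv")]] <- p(".edges.tsv")
  }
  invisible(paths)
}

# Orthology types linking a pair's partners to other species, collapsed to
# one label per edge ("-" when unknown / no orthologues).
edge_orthology_type <- function(rows, ortho) {
  if (is.null(ortho) || nrow(rows) == 0) {
    return(rep("-", nrow(rows)))
  }
  vapply(seq_len(nrow(rows)), function(i) {
    t_a <- ortho$homology_type[ortho$source_gene == rows$gene_a[i]]
    t_b <- ortho$homology_type[ortho$source_gene == rows$gene_b[i]]
    types <- sort(unique(c(t_a, t_b)))
    if (length(types) == 0) "-" else paste(types, collapse = "|")
  }, character(1))
}

#' Parse a SIF file back to an edge table
#'
#' @param path Path to a `.sif` file.
#' @return Tibble `gene_a`, `relation`, `gene_b` (pairs canonicalized).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) {
    stop("malformed SIF line(s): expected 'source<TAB>relation<TAB>target'",
      call. = FALSE
    )
  }
  out <- tibble(
    gene_a = vapply(parts, `[`, character(1), 1),
    relation = vapply(parts, `[`, character(1), 2),
    gene_b = vapply(parts, `[`, character(1), 3)
  )
  canonicalize_pairs(out)
}

#' Query interactions for a gene list
#'
#' Resolves the queried identifiers through a synonym table (when given) and
#' partitions all interactions touching the resolved genes into two disjoint
#' sets: interactions among the queried genes, and interactions between a
#' queried gene and any other protein. Known and predicted interactions are
#' both returned, labeled, with their scores; inputs that cannot be resolved
#' are reported rather than dropped silently.
#'
#' @param genes Character vector of gene identifiers or synonyms.
#' @param scored Scored interactions ([score_interactions()]).
#' @param synonyms Optional synonym table ([read_synonyms()]).
#' @return A list of class `interolog_query`: `among` (tibble of
#'   interactions with both partners queried), `beyond` (one partner
#'   queried), `resolved` (input -> gene id map), `unresolved` (character).
#' @export
query_interactions <- function(genes, scored, synonyms = NULL) {
  genes <- unique(genes)
  if (!is.null(synonyms)) {
    lookup <- dplyr::bind_rows(
      synonyms[, c("external_id", "gene_id")],
      tibble(
        external_id = unique(synonyms$gene_id),
        gene_id = unique(synonyms$gene_id)
      )
    ) |> dplyr::distinct(.data$external_id, .keep_all = TRUE)
    i <- match(genes, lookup$external_id)
    resolved <- tibble(query = genes, gene_id = lookup$gene_id[i])
  } else {
    resolved <- tibble(query = genes, gene_id = genes)
    resolved$gene_id[!resolved$gene_id %in%
      c(scored$gene_a, scored$gene_b)] <- NA_character_
  }
  unresolved <- resolved$query[is.na(resolved$gene_id)]
  ids <- unique(resolved$gene_id[!is.na(resolved$gene_id)])

  in_a <- scored$gene_a %in% ids
  in_b <- scored$gene_b %in% ids
  structure(
    list(
      among = scored[in_a & in_b, ],
      beyond = scored[xor(in_a, in_b), ],
      resolved = resolved[!is.na(resolved$gene_id), ],
      unresolved = unresolved
    ),
    class = "interolog_query"
  )
}

#' @export
print.interolog_query <- function(x, ...) {
  cat(sprintf(
    "Interaction query: %d gene(s) resolved, %d unresolved\n  among queried genes: %d interaction(s)\n  queried vs others:   %d interaction(s)\n",
    nrow(x$resolved), length(x$unresolved), nrow(x$among), nrow(x$beyond)
  ))
  invisible(x)
}

#' Filter predictions to the high-confidence set
#'
#' Keeps the interactions whose InteroScore reaches the cutoff (default 1.5,
#' the conventional high-confidence threshold) and reports the retained
#' percentage as the `"retained_pct"` attribute and a message.
#'
#' @param scored Scored interactions; typically the predicted subset.
#' @param cutoff Minimum InteroScore (>= 0).
#' @return The retained rows, with attribute `retained_pct`.
#' @export
filter_high_confidence <- function(scored, cutoff = 1.5) {
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  keep <- scored$intero_score >= cutoff
  pct <- if (nrow(scored) == 0) NA_real_ else 100 * mean(keep)
  if (!is.na(pct)) {
    message(sprintf(
      "retained %d/%d interactions (%.1f%%) at InteroScore >= %g",
      sum(keep), nrow(scored), pct, cutoff
    ))
  }
  structure(scored[keep, ], retained_pct = pct)
}
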