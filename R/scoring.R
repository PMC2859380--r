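#' OrthoScore: orthology strength of one protein toward one species
#'
#' Summarizes how well one protein is represented by its contributing
#' orthologues in another species. Identities are scaled relative to the
#' best orthologue (the maximum percent identity becomes 1), the relative
#' identities are reduced to the chosen resolution, squared (so weak
#' orthologues count much less than strong ones) and summed. A protein in a
#' one-to-one relationship therefore scores exactly 1; `n` equally good
#' orthologues score `n`.
#'
#' The `rounding` modes control the resolution of the relative identities
#' before squaring:
#' \describe{
#'   \item{`half_percent`}{floor to the nearest half percent (multiples of
#'     0.005). This is the default: the conventional statement of the score
#'     reports relative identities at half-percent resolution, rounded down
#'     (identities 92/87/72 give relative identities 1, 0.945, 0.780 and an
#'     OrthoScore of 2.501).}
#'   \item{`truncate3`}{truncate at the third decimal (92/87/72 gives 1,
#'     0.945, 0.782 and 2.505).}
#'   \item{`round3`}{round half-up at the third decimal.}
#'   \item{`none`}{no reduction.}
#' }
#'
#' @param identities Numeric vector of percent identities in (0, 100], one
#'   per contributing orthologue. Must be non-empty: a protein with no
#'   orthologue toward a species has no OrthoScore.
#' @param rounding Relative-identity resolution mode (see Details).
#' @return A single dimensionless score in `[1, length(identities)]`.
#' @examples
#' ortho_score(c(92, 87, 72)) # 2.501425 -> reported as 2.501
#' ortho_score(63) # exactly 1
#' @export
ortho_score <- function(identities,
                        rounding = c("half_percent", "truncate3", "round3", "none")) {
  rounding <- match.arg(rounding)
  if (length(identities) == 0) {
    stop("OrthoScore is undefined without contributing orthologues", call. = FALSE)
  }
  if (any(is.na(identities)) || any(identities <= 0) || any(identities > 100)) {
    stop("percent identities must lie in (0, 100]", call. = FALSE)
  }
  r <- identities / max(identities)
  r <- switch(rounding,
    half_percent = floor(r * 200) / 200,
    truncate3 = floor(r * 1000) / 1000,
    round3 = floor(r * 1000 + 0.5) / 1000,
    none = r
  )
  sum(r^2)
}

#' SingleSpeciesScore: support from one species for one interaction
#'
#' The product of the two partners' OrthoScores toward one supporting
#' species. Two one-to-one partners give 1; richer orthology in either
#' partner raises the score.
#'
#' @param ortho_a,ortho_b OrthoScores of the two partners (each >= 1).
#' @return Their product.
#' @examples
#' single_species_score(2.501, 1.00) # 2.501
#' @export
single_species_score <- function(ortho_a, ortho_b) {
  if (any(c(ortho_a, ortho_b) < 1)) {
    stop("OrthoScores are >= 1 by construction", call. = FALSE)
  }
  ortho_a * ortho_b
}

#' SpeciesScore: cross-species support for an interaction
#'
#' The sum of the SingleSpeciesScores over all species in which a supporting
#' (orthologous) interaction is observed, plus 1 when the interaction is
#' itself experimentally known in its home species. An interaction is never
#' penalized for species where the orthologues exist but no interaction has
#' been observed.
#'
#' @param single_scores Numeric vector of per-species SingleSpeciesScores
#'   (may be empty only for a home-known interaction).
#' @param home_known Is the interaction experimentally observed in its own
#'   species? (TRUE for known interactions, FALSE for predictions.)
#' @return The SpeciesScore.
#' @examples
#' species_score(c(1, 1, 1)) # a prediction seen in three species: 3
#' species_score(c(1, 2.501)) # 3.501
#' species_score(numeric(), home_known = TRUE) # an unconserved known PPI: 1
#' @export
species_score <- function(single_scores, home_known = FALSE) {
  if (length(single_scores) == 0 && !home_known) {
    stop(
      "an interaction needs at least one supporting species or a home observation",
      call. = FALSE
    )
  }
  sum(single_scores) + if (home_known) 1 else 0
}

#' ExperimentScore: number of distinct supporting experiments
#'
#' Counts the non-redundant experimental evidence behind an interaction,
#' pooled over the interaction itself and all its supporting interologs.
#' Each (experiment type, evidence id) record is counted once regardless of
#' how many databases reported it; with `count = "types"` each experiment
#' type is counted once overall. Interactions annotated only by a
#' BIND-style source carry the single sentinel record `protein_protein`
#' and score 1.
#'
#' @param evidence A tibble of evidence records with columns
#'   `experiment_type` and `evidence_id` (e.g. from the `evidence`
#'   list-column of a merged interactome).
#' @param count Count distinct `"records"` (type + id; default) or distinct
#'   `"types"`.
#' @return Integer count.
#' @export
experiment_score <- function(evidence, count = c("records", "types")) {
  count <- match.arg(count)
  if (is.null(evidence) || nrow(evidence) == 0) {
    return(0L)
  }
  if (count == "types") {
    return(length(unique(evidence$experiment_type)))
  }
  nrow(dplyr::distinct(evidence[, c("experiment_type", "evidence_id")]))
}

#' Per-experiment-type quality ratios against a reference interaction set
#'
#' For each experiment type, the fraction of the interactions it annotates
#' that are also present in an independent reference edge set (a STRING-like
#' interaction collection). Types annotating no interaction are omitted.
#'
#' @param interactome Merged interactome tibble ([merge_interactomes()]).
#' @param reference_edges Tibble of reference edges with columns `gene_a`,
#'   `gene_b` (orientation irrelevant), in the same identifier space.
#' @return A quality-ratio table: `experiment_type`, `annotated`,
#'   `in_reference`, `ratio` (each ratio in `[0, 1]`).
#' @examples
#' # a type annotating 4324 interactions of which 813 are in the reference
#' # yields ratio 813/4324 = 0.188
#' @export
quality_ratios <- function(interactome, reference_edges) {
  ref_keys <- if (nrow(reference_edges) > 0) {
    unique(pair_key(reference_edges$gene_a, reference_edges$gene_b))
  } else {
    character()
  }
  ann <- interactome |>
    dplyr::select("gene_a", "gene_b", "evidence") |>
    tidyr::unnest("evidence") |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .data$experiment_type)
  if (nrow(ann) == 0) {
    return(tibble(
      experiment_type = character(), annotated = integer(),
      in_reference = integer(), ratio = double()
    ))
  }
  ann$in_ref <- pair_key(ann$gene_a, ann$gene_b) %in% ref_keys
  ann |>
    dplyr::group_by(.data$experiment_type) |>
    dplyr::summarise(
      annotated = dplyr::n(),
      in_reference = sum(.data$in_ref),
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = .data$in_reference / .data$annotated) |>
    dplyr::arrange(.data$experiment_type)
}

#' Read/write a quality-ratio table as TSV
#'
#' Columns `experiment_type`, `annotated`, `in_reference`, `ratio`; on
#' reading, only `experiment_type` and `ratio` are required, so externally
#' supplied ratio tables can be used directly.
#'
#' @param ratios Quality-ratio tibble ([quality_ratios()]).
#' @param path TSV path.
#' @export
write_quality_ratios <- function(ratios, path) {
  readr::write_tsv(
    dplyr::arrange(ratios, .data$experiment_type), path,
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_quality_ratios
#' @export
read_quality_ratios <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      experiment_type = readr::col_character(),
      ratio = readr::col_double(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
  assert_columns(out, c("experiment_type", "ratio"), "quality-ratio table")
  if (any(out$ratio < 0 | out$ratio > 1, na.rm = TRUE)) {
    stop("quality ratios must lie in [0, 1]", call. = FALSE)
  }
  as_tibble(out)
}

#' ExperimentQualityScore: summed quality of an interaction's evidence
#'
#' The sum of the quality ratios of the distinct experiment types annotating
#' an interaction. Types absent from the ratio table contribute 0.
#'
#' @param evidence_types Character vector of experiment types (duplicates
#'   are counted once).
#' @param ratios Quality-ratio table (or a named numeric vector of ratios).
#' @return The summed score.
#' @examples
#' rt <- tibble::tibble(
#'   experiment_type = c("MI:0019(coimmunoprecipitation)", "MI:0398(two hybrid pooling)"),
#'   ratio = c(0.188, 0.718)
#' )
#' experiment_quality_score(rt$experiment_type, rt) # 0.906
#' @export
experiment_quality_score <- function(evidence_types, ratios) {
  types <- unique(evidence_types)
  if (length(types) == 0) {
    return(0)
  }
  if (is.numeric(ratios)) {
    ratios <- tibble(experiment_type = names(ratios), ratio = unname(ratios))
  }
  i <- match(types, ratios$experiment_type)
  sum(ifelse(is.na(i), 0, ratios$ratio[i]))
}

#' InteroScore: the unified confidence measure
#'
#' The product of the SpeciesScore and the ExperimentScore, plus the
#' ExperimentQualityScore. Monotone nondecreasing in each component: more
#' supporting species, more experiments, or higher-quality experiment types
#' never lower it.
#'
#' @param species_score,experiment_score,experiment_quality_score The three
#'   components (vectorized).
#' @return The InteroScore(s).
#' @examples
#' intero_score(3, 2, 0.906) # 6.906
#' @export
intero_score <- function(species_score, experiment_score,
                         experiment_quality_score = 0) {
  species_score * experiment_score + experiment_quality_score
}

#' Score known and predicted interactions
#'
#' Computes the full confidence bundle for every known interaction and
#' (optionally) every prediction: per-supporting-species OrthoScores and
#' SingleSpeciesScores, the SpeciesScore (with the home-species contribution
#' of 1 for known interactions), the ExperimentScore over the evidence
#' pooled across the interaction and its supporting interologs, the
#' ExperimentQualityScore, the InteroScore, and the SpeciesNotation string.
#'
#' Contributing orthologues are restricted to those that participate in at
#' least one supporting known interaction in the given source species, and
#' the relative-identity maximum is taken among those contributors only.
#' Identities are taken from the orthology record directed from the scored
#' interaction's species toward the supporting species (the reciprocal
#' record's identity is used as a fallback when only that direction exists).
#'
#' @param known Merged known interactome tibble across species.
#' @param predictions Predictions tibble from [predict_interologues()], or
#'   `NULL` to score known interactions only.
#' @param ortho Orthology map tibble.
#' @param ratios Quality-ratio table ([quality_ratios()]); `NULL` gives
#'   every type quality 0.
#' @param registry Species registry (letters for SpeciesNotation).
#' @param rounding Relative-identity mode, see [ortho_score()].
#' @param experiment_count `"records"` or `"types"`, see
#'   [experiment_score()].
#' @return A tibble with one row per interaction: `species`, `gene_a`,
#'   `gene_b`, `origin`, `species_score`, `experiment_score`,
#'   `experiment_quality_score`, `intero_score`, `species_notation`,
#'   `supporting_species`, and list-column `support_scores` of per-species
#'   detail (`source_species`, `ortho_score_a`, `ortho_score_b`,
#'   `single_species_score`).
#' @export
score_interactions <- function(known, predictions = NULL, ortho,
                               ratios = NULL,
                               registry = default_species_registry(),
                               rounding = "half_percent",
                               experiment_count = "records") {
  registry <- validate_registry(registry)
  rows <- known |>
    dplyr::select("species", "gene_a", "gene_b", "evidence") |>
    dplyr::mutate(origin = "known")
  if (!is.null(predictions) && nrow(predictions) > 0) {
    rows <- dplyr::bind_rows(
      rows,
      predictions |>
        dplyr::select("species", "gene_a", "gene_b") |>
        dplyr::mutate(evidence = list(NULL), origin = "predicted")
    )
  }
  rows$id <- seq_len(nrow(rows))

  sup <- find_supports(
    rows[, c("id", "species", "gene_a", "gene_b")],
    known, ortho
  )
  sup_by_id <- split(sup, sup$id)

  # evidence lookup for supporting known interactions
  known_key <- paste(known$species, known$gene_a, known$gene_b, sep = "\r")
  identity_of <- make_identity_lookup(ortho)

  detail <- vector("list", nrow(rows))
  scores <- matrix(0, nrow(rows), 3,
    dimnames = list(NULL, c("ss", "es", "eqs"))
  )
  for (i in seq_len(nrow(rows))) {
    s_i <- sup_by_id[[as.character(rows$id[i])]]
    home <- rows$species[i]
    per_species <- if (is.null(s_i) || nrow(s_i) == 0) {
      tibble(
        source_species = character(), ortho_score_a = double(),
        ortho_score_b = double(), single_species_score = double()
      )
    } else {
      s_i |>
        dplyr::group_by(.data$source_species) |>
        dplyr::summarise(
          ortho_score_a = ortho_score(
            identity_of(home, .data$source_species[1], rows$gene_a[i],
              unique(.data$contributor_a)
            ),
            rounding = rounding
          ),
          ortho_score_b = ortho_score(
            identity_of(home, .data$source_species[1], rows$gene_b[i],
              unique(.data$contributor_b)
            ),
            rounding = rounding
          ),
          .groups = "drop"
        ) |>
        dplyr::mutate(
          single_species_score = .data$ortho_score_a * .data$ortho_score_b
        )
    }
    detail[[i]] <- per_species

    home_known <- rows$origin[i] == "known"
    scores[i, "ss"] <- species_score(per_species$single_species_score,
      home_known = home_known
    )

    own_ev <- if (home_known) rows$evidence[[i]] else NULL
    sup_ev <- if (!is.null(s_i) && nrow(s_i) > 0) {
      hit <- match(
        unique(paste(s_i$source_species, s_i$source_gene_a,
          s_i$source_gene_b,
          sep = "\r"
        )),
        known_key
      )
      dplyr::bind_rows(known$evidence[hit[!is.na(hit)]])
    } else {
      NULL
    }
    ev <- dplyr::bind_rows(own_ev, sup_ev)
    scores[i, "es"] <- experiment_score(ev, count = experiment_count)
    scores[i, "eqs"] <- if (is.null(ratios) || nrow(ev) == 0) {
      0
    } else {
      experiment_quality_score(ev$experiment_type, ratios)
    }
  }

  notation <- species_notation(
    rows[, c("species", "gene_a", "gene_b", "origin")],
    known, ortho, registry
  )

  tibble(
    species = rows$species,
    gene_a = rows$gene_a,
    gene_b = rows$gene_b,
    origin = rows$origin,
    species_score = unname(scores[, "ss"]),
    experiment_score = as.integer(unname(scores[, "es"])),
    experiment_quality_score = unname(scores[, "eqs"]),
    intero_score = unname(intero_score(
      scores[, "ss"], scores[, "es"], scores[, "eqs"]
    )),
    species_notation = notation,
    supporting_species = vapply(
      detail,
      function(d) paste(sort(d$source_species), collapse = ","),
      character(1)
    ),
    support_scores = detail
  )
}

# Closure mapping (home species, other species, home gene, other genes) to
# percent identities; prefers the record directed home -> other.
make_identity_lookup <- function(ortho) {
  fwd_key <- paste(ortho$source_species, ortho$target_species,
    ortho$source_gene, ortho$target_gene,
    sep = "\r"
  )
  function(home, other, home_gene, other_genes) {
    keys <- paste(home, other, home_gene, other_genes, sep = "\r")
    i <- match(keys, fwd_key)
    rev_keys <- paste(other, home, other_genes, home_gene, sep = "\r")
    j <- match(rev_keys, fwd_key)
    ids <- ifelse(is.na(i), ortho$percent_identity[j],
      ortho$percent_identity[i]
    )
    ids[!is.na(ids)]
  }
}

#' Write scored interactions as TSV
#'
#' Columns: pair, species, origin, the four scores (3 decimals, half-up) and
#' the SpeciesNotation; sorted canonically so output is deterministic.
#'
#' @param scored Output of [score_interactions()].
#' @param path Output TSV path.
#' @export
write_scores <- function(scored, path) {
  scored |>
    dplyr::arrange(.data$species, .data$gene_a, .data$gene_b) |>
    dplyr::transmute(
      .data$species, .data$gene_a, .data$gene_b, .data$origin,
      species_score = format_score(.data$species_score),
      experiment_score = .data$experiment_score,
      experiment_quality_score = format_score(.data$experiment_quality_score),
      intero_score = format_score(.data$intero_score),
      species_notation = .data$species_notation
    ) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
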