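#' @title Interolog detection and prediction
#' @description Internal helpers build, for a pair (A, B) living in species
#'   `h`, the set of orthologous candidate pairs in another species `s`; the
#'   exported functions use them to detect conserved interologs and to
#'   predict new interactions.
#' @name interolog
NULL

# Symmetric orthology view from `home` toward `other`: one row per
# (home_gene, other_gene) relation. Directed records home->other are
# preferred; reversed records fill in relations only stated the other way
# (their identity is the other protein's, flagged direct = FALSE).
ortho_view <- function(ortho, home, other) {
  fwd <- ortho[ortho$source_species == home & ortho$target_species == other, ]
  rev <- ortho[ortho$source_species == other & ortho$target_species == home, ]
  fwd <- tibble(
    home_gene = fwd$source_gene, other_gene = fwd$target_gene,
    homology_type = fwd$homology_type,
    percent_identity = fwd$percent_identity, direct = TRUE
  )
  rev <- tibble(
    home_gene = rev$target_gene, other_gene = rev$source_gene,
    homology_type = rev$homology_type,
    percent_identity = rev$percent_identity, direct = FALSE
  )
  dplyr::bind_rows(fwd, rev) |>
    dplyr::arrange(dplyr::desc(.data$direct)) |>
    dplyr::distinct(.data$home_gene, .data$other_gene, .keep_all = TRUE)
}

# Known interactions of one species as a canonical pair tibble.
known_pairs_of <- function(known, s) {
  k <- known[known$species == s, c("gene_a", "gene_b")]
  canonicalize_pairs(as_tibble(k))
}

# For pair rows (id, species, gene_a, gene_b), all orthologous candidate
# pairs in species `s`: cand_a/cand_b is the canonical candidate pair,
# contributor_a/contributor_b the s-species gene aligned to the home
# partner gene_a/gene_b.
ortho_candidate_pairs <- function(pairs, ortho, s) {
  out <- list()
  for (h in setdiff(unique(pairs$species), s)) {
    p <- pairs[pairs$species == h, ]
    v <- ortho_view(ortho, home = h, other = s)
    if (nrow(v) == 0 || nrow(p) == 0) next
    va <- v[, c("home_gene", "other_gene")]
    cand <- p |>
      dplyr::inner_join(va,
        by = c(gene_a = "home_gene"),
        relationship = "many-to-many"
      ) |>
      dplyr::rename(orth_a = "other_gene") |>
      dplyr::inner_join(va,
        by = c(gene_b = "home_gene"),
        relationship = "many-to-many"
      ) |>
      dplyr::rename(orth_b = "other_gene")
    if (nrow(cand) == 0) next
    cand$cand_a <- pmin(cand$orth_a, cand$orth_b)
    cand$cand_b <- pmax(cand$orth_a, cand$orth_b)
    out[[h]] <- dplyr::mutate(cand, cand_species = s)
  }
  if (length(out) == 0) {
    return(tibble(
      id = integer(), species = character(), gene_a = character(),
      gene_b = character(), orth_a = character(), orth_b = character(),
      cand_a = character(), cand_b = character(), cand_species = character()
    ))
  }
  dplyr::bind_rows(out)
}

# Supporting known interologs of arbitrary pairs: for each pair (a, b) in
# species h, every known interaction in another species s between
# orthologues of a and b. contributor_a is the s-gene orthologous to a that
# participates in the supporting interaction.
find_supports <- function(pairs, known, ortho) {
  res <- list()
  for (s in unique(known$species)) {
    cand <- ortho_candidate_pairs(pairs, ortho, s)
    if (nrow(cand) == 0) next
    ks <- known_pairs_of(known, s)
    hit <- dplyr::inner_join(cand, ks,
      by = c(cand_a = "gene_a", cand_b = "gene_b")
    )
    if (nrow(hit) == 0) next
    res[[s]] <- tibble(
      id = hit$id,
      source_species = s,
      source_gene_a = hit$cand_a,
      source_gene_b = hit$cand_b,
      contributor_a = hit$orth_a,
      contributor_b = hit$orth_b
    )
  }
  if (length(res) == 0) {
    return(tibble(
      id = integer(), source_species = character(),
      source_gene_a = character(), source_gene_b = character(),
      contributor_a = character(), contributor_b = character()
    ))
  }
  dplyr::distinct(dplyr::bind_rows(res))
}

#' Detect interologs conserved between known interactomes
#'
#' For every ordered species pair (s, t), finds the known interactions (A, B)
#' of s for which some orthologue pair (A', B') is itself a known interaction
#' in t. Bookkeeping is directional: "interactions of s conserved in t" and
#' "interactions of t conserved in s" are reported separately (the counts
#' need not match, because one interaction in s can be orthologous to several
#' in t and vice versa).
#'
#' @param known A merged interactome tibble covering at least two species
#'   (see [merge_interactomes()]).
#' @param ortho An orthology map tibble ([read_orthology()]).
#' @return A tibble with one row per conserved correspondence:
#'   `source_species`, `target_species`, `gene_a`, `gene_b` (the source
#'   interaction), `target_gene_a`, `target_gene_b` (the orthologous known
#'   interaction in the target species).
#' @seealso [conserved_counts()], [predict_interologues()]
#' @export
find_conserved <- function(known, ortho) {
  pairs <- known |>
    dplyr::select("species", "gene_a", "gene_b") |>
    dplyr::distinct() |>
    dplyr::mutate(id = dplyr::row_number())
  sup <- find_supports(pairs, known, ortho)
  if (nrow(sup) == 0) {
    return(tibble(
      source_species = character(), target_species = character(),
      gene_a = character(), gene_b = character(),
      target_gene_a = character(), target_gene_b = character()
    ))
  }
  joined <- dplyr::inner_join(pairs, sup, by = "id")
  tibble(
    source_species = joined$species,
    target_species = joined$source_species,
    gene_a = joined$gene_a, gene_b = joined$gene_b,
    target_gene_a = joined$source_gene_a,
    target_gene_b = joined$source_gene_b
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(
      .data$source_species, .data$target_species,
      .data$gene_a, .data$gene_b
    )
}

#' Count conserved interactions per directed species pair
#'
#' Tallies, for each ordered (source, target) species pair, how many distinct
#' source interactions have at least one orthologous known counterpart in the
#' target species.
#'
#' @param conserved Output of [find_conserved()].
#' @return Tibble `source_species`, `target_species`, `n_conserved`.
#' @export
conserved_counts <- function(conserved) {
  conserved |>
    dplyr::distinct(
      .data$source_species, .data$target_species,
      .data$gene_a, .data$gene_b
    ) |>
    dplyr::count(.data$source_species, .data$target_species,
      name = "n_conserved"
    )
}

#' Predict interologs in a target species
#'
#' For every known interaction (A, B) in another species whose two partners
#' both have orthologues in the target species, every candidate orthologue
#' pair (A', B') is enumerated (the full Cartesian product under one-to-many
#' and many-to-many orthology, excluding pairs whose two members are the same
#' gene). Candidates already present in the target species' known interactome
#' are excluded: predictions and known interactions are disjoint by
#' construction. A candidate supported by several source species or several
#' source interactions becomes a single prediction with all supports listed.
#'
#' @param known Merged interactome tibble across species.
#' @param ortho Orthology map tibble.
#' @param target Target species code(s); defaults to every species present in
#'   `known`.
#' @return A tibble of predictions: `species`, `gene_a`, `gene_b`, `origin`
#'   (`"predicted"`), `n_supports`, `supporting_species` (comma-joined), and
#'   list-column `supports` of tibbles with `source_species`,
#'   `source_gene_a`, `source_gene_b` (the supporting known interaction) and
#'   `contributor_a`, `contributor_b` (the source genes orthologous to the
#'   predicted partners).
#' @export
predict_interologues <- function(known, ortho, target = NULL) {
  target <- target %||% sort(unique(known$species))
  out <- lapply(target, function(t) predict_one_target(known, ortho, t))
  dplyr::bind_rows(out)
}

predict_one_target <- function(known, ortho, target) {
  sources <- setdiff(unique(known$species), target)
  src_pairs <- known |>
    dplyr::filter(.data$species %in% sources) |>
    dplyr::distinct(.data$species, .data$gene_a, .data$gene_b) |>
    dplyr::mutate(id = dplyr::row_number())
  cand <- ortho_candidate_pairs(src_pairs, ortho, target)
  empty <- tibble(
    species = character(), gene_a = character(), gene_b = character(),
    origin = character(), n_supports = integer(),
    supporting_species = character(), supports = list()
  )
  if (nrow(cand) == 0) {
    return(empty)
  }
  cand <- cand[cand$cand_a != cand$cand_b, ]
  kt <- known_pairs_of(known, target)
  cand <- dplyr::anti_join(cand, kt,
    by = c(cand_a = "gene_a", cand_b = "gene_b")
  )
  if (nrow(cand) == 0) {
    return(empty)
  }
  # align source contributors to the canonical candidate pair
  swap <- cand$orth_a > cand$orth_b
  sup <- tibble(
    gene_a = cand$cand_a,
    gene_b = cand$cand_b,
    source_species = cand$species,
    source_gene_a = cand$gene_a,
    source_gene_b = cand$gene_b,
    contributor_a = ifelse(swap, cand$gene_b, cand$gene_a),
    contributor_b = ifelse(swap, cand$gene_a, cand$gene_b)
  ) |>
    dplyr::distinct()
  sup |>
    tidyr::nest(supports = c(
      "source_species", "source_gene_a", "source_gene_b",
      "contributor_a", "contributor_b"
    )) |>
    dplyr::mutate(
      species = target,
      origin = "predicted",
      n_supports = vapply(.data$supports, nrow, integer(1)),
      supporting_species = vapply(
        .data$supports,
        function(s) paste(sort(unique(s$source_species)), collapse = ","),
        character(1)
      )
    ) |>
    dplyr::select(
      "species", "gene_a", "gene_b", "origin", "n_supports",
      "supporting_species", "supports"
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' SpeciesNotation strings
#'
#' Encodes, per interaction, in which species it is observed and in which it
#' merely could exist. One letter (the genus initial from the registry, in
#' registry order) is emitted for each species where both partners have
#' orthologues, or which is the interaction's home species: uppercase when an
#' (orthologous) interaction is experimentally observed there, lowercase when
#' only the orthologues exist. Species lacking orthologues for either partner
#' are omitted. The home letter of a predicted interaction is lowercase by
#' definition; for a known interaction it is uppercase.
#'
#' @param interactions Tibble with columns `species`, `gene_a`, `gene_b`,
#'   `origin` (`"known"` or `"predicted"`).
#' @param known Merged known interactome tibble across all species.
#' @param ortho Orthology map tibble.
#' @param registry Species registry fixing letters and their order.
#' @return Character vector of notation strings, one per input row.
#' @export
species_notation <- function(interactions, known, ortho,
                             registry = default_species_registry()) {
  registry <- validate_registry(registry)
  pairs <- interactions |>
    dplyr::select("species", "gene_a", "gene_b", "origin") |>
    dplyr::mutate(id = dplyr::row_number())
  sup <- find_supports(pairs, known, ortho)
  observed <- split(sup$source_species, sup$id)

  # per registry species: do both partners have orthologues there?
  has_orth <- matrix(FALSE, nrow(pairs), nrow(registry),
    dimnames = list(NULL, registry$code)
  )
  for (s in registry$code) {
    for (h in setdiff(unique(pairs$species), s)) {
      v <- ortho_view(ortho, home = h, other = s)
      rows <- which(pairs$species == h)
      has_orth[rows, s] <- pairs$gene_a[rows] %in% v$home_gene &
        pairs$gene_b[rows] %in% v$home_gene
    }
  }

  vapply(seq_len(nrow(pairs)), function(i) {
    obs <- observed[[as.character(i)]] %||% character()
    letters_out <- character()
    for (j in seq_len(nrow(registry))) {
      s <- registry$code[j]
      lt <- registry$genus_letter[j]
      if (s == pairs$species[i]) {
        letters_out <- c(
          letters_out,
          if (pairs$origin[i] == "known") lt else tolower(lt)
        )
      } else if (has_orth[i, s]) {
        letters_out <- c(
          letters_out,
          if (s %in% obs) lt else tolower(lt)
        )
      }
    }
    paste(letters_out, collapse = "")
  }, character(1))
}
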