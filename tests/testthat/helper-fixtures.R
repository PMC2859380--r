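# Small in-code builders shared across tests.

evidence_rec <- function(id, type = "MI:0018(two hybrid)", db = "intactdb") {
  tibble::tibble(experiment_type = type, evidence_id = id, source_db = db)
}

known_table <- function(species, gene_a, gene_b, evidence = NULL) {
  n <- length(species)
  if (is.null(evidence)) {
    evidence <- lapply(sprintf("E%03d", seq_len(n)), evidence_rec)
  }
  tibble::tibble(
    species = species,
    gene_a = pmin(gene_a, gene_b),
    gene_b = pmax(gene_a, gene_b),
    origin = "known",
    self = gene_a == gene_b,
    n_evidence = vapply(evidence, nrow, integer(1)),
    evidence = evidence
  )
}

ortho_rows <- function(source_gene, source_species, target_gene,
                       target_species, homology_type = "one2one",
                       percent_identity = 80, reciprocal = TRUE) {
  fwd <- tibble::tibble(
    source_gene = source_gene, source_species = source_species,
    target_gene = target_gene, target_species = target_species,
    homology_type = homology_type, percent_identity = percent_identity
  )
  if (!reciprocal) {
    return(fwd)
  }
  dplyr::bind_rows(fwd, tibble::tibble(
    source_gene = target_gene, source_species = target_species,
    target_gene = source_gene, target_species = source_species,
    homology_type = homology_type, percent_identity = percent_identity
  ))
}

# The worked one-to-many scoring scenario: a fly pair predicted from a
# one-to-one worm interolog plus three human interologues at identities
# 92/87/72 on one partner.
worked_example_inputs <- function() {
  ortho <- dplyr::bind_rows(
    ortho_rows("dmel_A", "dmel", c("hsap_A1", "hsap_A2", "hsap_A3"), "hsap",
      homology_type = "one2many", percent_identity = c(92, 87, 72)
    ),
    ortho_rows("dmel_A", "dmel", "cele_A", "cele", percent_identity = 70),
    ortho_rows("dmel_B", "dmel", "hsap_B", "hsap", percent_identity = 66),
    ortho_rows("dmel_B", "dmel", "cele_B", "cele", percent_identity = 64)
  )
  known <- known_table(
    species = c("hsap", "hsap", "hsap", "cele"),
    gene_a = c("hsap_A1", "hsap_A2", "hsap_A3", "cele_A"),
    gene_b = c("hsap_B", "hsap_B", "hsap_B", "cele_B")
  )
  list(ortho = ortho, known = known)
}

# Modular network with local "predicted" edges; the known part is
# small-world (dense random inter-module links), predictions are strictly
# within-module, mirroring how interolog prediction densifies complexes.
modular_networks <- function(n = 500, n_mod = 20, seed = 1,
                             known_per_mod = 40, cross = 400,
                             pred_per_mod = 15) {
  withr::with_seed(seed, {
    nodes <- sprintf("g%03d", seq_len(n))
    mod <- rep(seq_len(n_mod), length.out = n)
    pick_edges <- function(pool, m) {
      got <- character(0)
      while (length(got) < m) {
        pr <- sort(sample(pool, 2))
        got <- union(got, paste(pr[1], pr[2], sep = "\r"))
      }
      parts <- strsplit(got, "\r", fixed = TRUE)
      tibble::tibble(
        gene_a = vapply(parts, `[`, character(1), 1),
        gene_b = vapply(parts, `[`, character(1), 2)
      )
    }
    known <- dplyr::bind_rows(lapply(seq_len(n_mod), function(m) {
      pick_edges(nodes[mod == m], known_per_mod)
    }))
    known <- dplyr::distinct(dplyr::bind_rows(known, pick_edges(nodes, cross)))
    pred <- dplyr::bind_rows(lapply(seq_len(n_mod), function(m) {
      pick_edges(nodes[mod == m], pred_per_mod)
    }))
    k <- paste(known$gene_a, known$gene_b)
    pred <- pred[!paste(pred$gene_a, pred$gene_b) %in% k, ]
    list(known = known, predicted = dplyr::distinct(pred))
  })
}

empty_ortho_map <- function() {
  tibble::tibble(
    source_gene = character(), source_species = character(),
    target_gene = character(), target_species = character(),
    homology_type = character(), percent_identity = double()
  )
}

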