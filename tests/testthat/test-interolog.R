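test_that("a planted conserved pair is reported in both directions", {
  ortho <- dplyr::bind_rows(
    ortho_rows("h1", "hsap", "m1", "mmus"),
    ortho_rows("h2", "hsap", "m2", "mmus"),
    ortho_rows("h3", "hsap", "m3", "mmus")
  )
  known <- known_table(
    species = c("hsap", "mmus", "hsap"),
    gene_a = c("h1", "m1", "h1"),
    gene_b = c("h2", "m2", "h3") # h1-h3 has orthologues but no mouse edge
  )
  cons <- find_conserved(known, ortho)
  counts <- conserved_counts(cons)
  expect_equal(nrow(counts), 2)
  expect_equal(counts$n_conserved, c(1, 1))
  expect_false(any(cons$gene_b == "h3")) # orthologues alone are not enough
})

test_that("conserved detection matches the planted fixture per direction", {
  fx <- generate_fixture(
    fixture_spec(n_genes = 30, n_conserved = 10, n_predictable = 0, seed = 7),
    outdir = NULL
  )
  known <- merge_interactomes(
    dplyr::mutate(fx$data$edges,
      experiment_type = "protein_protein",
      evidence_id = paste0("r", dplyr::row_number()), source_db = "x"
    ) |>
      dplyr::rename(interactor_a = "gene_a", interactor_b = "gene_b")
  )
  cons <- find_conserved(known, fx$data$ortho)
  planted <- fx$ground_truth$planted_conserved
  for (i in seq_len(nrow(planted))) {
    fwd <- cons$source_species == planted$species_1[i] &
      cons$gene_a == planted$gene_1a[i] & cons$gene_b == planted$gene_1b[i] &
      cons$target_species == planted$species_2[i]
    rev <- cons$source_species == planted$species_2[i] &
      cons$gene_a == planted$gene_2a[i] & cons$gene_b == planted$gene_2b[i] &
      cons$target_species == planted$species_1[i]
    expect_true(any(fwd))
    expect_true(any(rev))
  }
})

test_that("prediction handles one2one, exclusion, and one2many enumeration", {
  # one2one x one2one known in one species -> exactly one prediction
  ortho <- dplyr::bind_rows(
    ortho_rows("h1", "hsap", "m1", "mmus"),
    ortho_rows("h2", "hsap", "m2", "mmus")
  )
  known <- known_table("hsap", "h1", "h2")
  preds <- predict_interologues(known, ortho, target = "mmus")
  expect_equal(nrow(preds), 1)
  expect_equal(preds$n_supports, 1)
  expect_equal(sort(c(preds$gene_a, preds$gene_b)), c("m1", "m2"))

  # already known in the target -> no prediction
  known2 <- known_table(c("hsap", "mmus"), c("h1", "m1"), c("h2", "m2"))
  expect_equal(nrow(predict_interologues(known2, ortho, target = "mmus")), 0)

  # one2many (3 orthologues) x one2one -> 3 predictions
  ortho3 <- dplyr::bind_rows(
    ortho_rows("h1", "hsap", c("m1a", "m1b", "m1c"), "mmus",
      homology_type = "one2many", percent_identity = c(92, 87, 72)
    ),
    ortho_rows("h2", "hsap", "m2", "mmus")
  )
  preds3 <- predict_interologues(known, ortho3, target = "mmus")
  expect_equal(nrow(preds3), 3)
  expect_setequal(
    paste(pmin(preds3$gene_a, preds3$gene_b), pmax(preds3$gene_a, preds3$gene_b)),
    oracle_predict(known, ortho3, "mmus")
  )
})

test_that("predictions agree with the exhaustive oracle on fixtures", {
  for (seed in c(3, 17)) {
    fx <- generate_fixture(
      fixture_spec(n_genes = 25, n_conserved = 4, n_predictable = 4, seed = seed),
      outdir = NULL
    )
    known <- merge_interactomes(
      dplyr::mutate(fx$data$edges,
        experiment_type = "protein_protein",
        evidence_id = paste0("r", dplyr::row_number()), source_db = "x"
      ) |>
        dplyr::rename(interactor_a = "gene_a", interactor_b = "gene_b")
    )
    for (t in unique(known$species)) {
      preds <- predict_interologues(known, fx$data$ortho, target = t)
      got <- sort(paste(preds$gene_a, preds$gene_b))
      expect_equal(got, oracle_predict(known, fx$data$ortho, t))
      # predicted and known sets are disjoint
      kt <- known[known$species == t, ]
      expect_equal(
        length(intersect(got, paste(kt$gene_a, kt$gene_b))), 0
      )
    }
  }
})

test_that("species notation follows the observed/potential case rules", {
  # known only in human, orthologues (both partners) in mouse only -> "Hm"
  ortho <- dplyr::bind_rows(
    ortho_rows("h1", "hsap", "m1", "mmus"),
    ortho_rows("h2", "hsap", "m2", "mmus"),
    ortho_rows("h1", "hsap", "d1", "dmel") # only one partner in fly
  )
  known <- known_table("hsap", "h1", "h2")
  expect_equal(species_notation(known, known, ortho), "Hm")

  # prediction in fly observed in human, worm, yeast -> "HdCS"
  ortho_t3 <- dplyr::bind_rows(
    ortho_rows("dmel_A", "dmel", "hsap_A1", "hsap"),
    ortho_rows("dmel_B", "dmel", "hsap_B", "hsap"),
    ortho_rows("dmel_A", "dmel", "cele_A", "cele"),
    ortho_rows("dmel_B", "dmel", "cele_B", "cele"),
    ortho_rows("dmel_A", "dmel", "scer_A", "scer"),
    ortho_rows("dmel_B", "dmel", "scer_B", "scer")
  )
  known_t3 <- known_table(
    c("hsap", "cele", "scer"),
    c("hsap_A1", "cele_A", "scer_A"),
    c("hsap_B", "cele_B", "scer_B")
  )
  pred <- tibble::tibble(
    species = "dmel", gene_a = "dmel_A", gene_b = "dmel_B",
    origin = "predicted"
  )
  expect_equal(species_notation(pred, known_t3, ortho_t3), "HdCS")

  # no orthologues anywhere, known in yeast only -> "S"
  solo <- known_table("scer", "y1", "y2")
  expect_equal(species_notation(solo, solo, empty_ortho_map()), "S")
})

test_that("hubs with many known edges gain proportionally fewer predictions", {
  # designed fixture: the human hub's interactions are all already known in
  # mouse; fresh mouse interactions exist only among the hub-free periphery
  genes <- sprintf("g%02d", 1:20)
  ortho <- dplyr::bind_rows(lapply(genes, function(g) {
    ortho_rows(paste0("h_", g), "hsap", paste0("m_", g), "mmus")
  }))
  hub_edges <- known_table(
    rep("mmus", 10),
    rep("m_g01", 10), paste0("m_", genes[2:11])
  )
  ring <- known_table(
    rep("hsap", 8),
    paste0("h_", genes[12:19]), paste0("h_", genes[c(13:19, 12)])
  )
  known <- dplyr::bind_rows(hub_edges, ring)
  preds <- predict_interologues(known, ortho, target = "mmus")
  deg <- function(edges) {
    table(factor(c(edges$gene_a, edges$gene_b), levels = paste0("m_", genes)))
  }
  known_deg <- as.integer(deg(known[known$species == "mmus", ]))
  pred_deg <- as.integer(deg(preds))
  rho <- suppressWarnings(
    cor(known_deg, pred_deg, method = "spearman")
  )
  expect_lt(rho, 0)
})
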