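test_that("ortho_score reproduces the canonical worked values", {
  expect_equal(round(ortho_score(c(92, 87, 72)), 3), 2.501)
  expect_equal(ortho_score(63), 1)
  expect_equal(ortho_score(c(80, 80)), 2)
  # alternative resolution modes of the relative identities
  expect_equal(round(ortho_score(c(92, 87, 72), rounding = "truncate3"), 3), 2.505)
  expect_equal(
    ortho_score(c(92, 87, 72), rounding = "none"),
    1 + (87 / 92)^2 + (72 / 92)^2
  )
  expect_error(ortho_score(numeric()), "undefined")
  expect_error(ortho_score(c(50, 120)), "0, 100")
})

test_that("ortho_score is scale-invariant and bounded by [1, n]", {
  withr::with_seed(42, {
    for (i in 1:25) {
      ids <- runif(sample(1:6, 1), 10, 100)
      s <- ortho_score(ids)
      expect_gte(s, 1)
      expect_lte(s, length(ids))
      expect_equal(ortho_score(ids * 0.5), s)
    }
  })
  expect_equal(ortho_score(rep(55, 4)), 4) # equal identities reach the bound
})

test_that("single-species and species scores combine as stated", {
  expect_equal(single_species_score(1, 1), 1)
  expect_equal(single_species_score(2.501, 1), 2.501)
  expect_equal(single_species_score(2, 3), 6)
  expect_error(single_species_score(0.5, 1), ">= 1")

  expect_equal(species_score(c(1, 1, 1)), 3)
  expect_equal(species_score(c(1, 2.501)), 3.501)
  expect_equal(species_score(numeric(), home_known = TRUE), 1)
  expect_equal(species_score(c(1, 1), home_known = TRUE), 3)
  expect_error(species_score(numeric()), "supporting species")
})

test_that("experiment_score counts distinct records (or types)", {
  bind_only <- evidence_rec("binddb:row1", type = "protein_protein", db = "binddb")
  expect_equal(experiment_score(bind_only), 1)
  dup <- dplyr::bind_rows(
    evidence_rec("E1", db = "intactdb"),
    evidence_rec("E1", db = "dipdb")
  )
  expect_equal(experiment_score(dup), 1)
  three <- dplyr::bind_rows(
    evidence_rec("E1"), evidence_rec("E2"),
    evidence_rec("E3", type = "MI:0019(coimmunoprecipitation)")
  )
  expect_equal(experiment_score(three), 3)
  expect_equal(experiment_score(three, count = "types"), 2)
  expect_equal(experiment_score(NULL), 0L)
})

test_that("quality ratios are exact fractions of reference coverage", {
  # 4 interactions annotated by e1, 3 of them in the reference -> 0.75;
  # e2 annotates 2, none in the reference -> 0
  known <- known_table(
    rep("hsap", 4), paste0("a", 1:4), paste0("b", 1:4),
    evidence = list(
      dplyr::bind_rows(evidence_rec("E1"), evidence_rec("E5", type = "e2")),
      evidence_rec("E2"), evidence_rec("E3"),
      dplyr::bind_rows(evidence_rec("E4"), evidence_rec("E6", type = "e2"))
    )
  )
  ref <- tibble::tibble(gene_a = paste0("a", 1:3), gene_b = paste0("b", 1:3))
  qr <- quality_ratios(known, ref)
  expect_equal(qr$ratio[qr$experiment_type == "MI:0018(two hybrid)"], 0.75)
  expect_equal(qr$ratio[qr$experiment_type == "e2"], 0.5)
  # empty reference: all ratios 0
  qr0 <- quality_ratios(known, ref[0, ])
  expect_true(all(qr0$ratio == 0))
  expect_true(all(qr$ratio >= 0 & qr$ratio <= 1))
  # a reference superset adding unannotated pairs changes nothing
  ref_sup <- dplyr::bind_rows(
    ref, tibble::tibble(gene_a = "zz1", gene_b = "zz2")
  )
  expect_equal(quality_ratios(known, ref_sup), qr)
})

test_that("experiment quality scores sum distinct types only", {
  rt <- tibble::tibble(
    experiment_type = c(
      "MI:0019(coimmunoprecipitation)", "MI:0398(two hybrid pooling)"
    ),
    ratio = c(0.188, 0.718)
  )
  expect_equal(
    experiment_quality_score(rt$experiment_type, rt), 0.906
  )
  expect_equal(experiment_quality_score(character(), rt), 0)
  expect_equal(
    experiment_quality_score(rep("MI:0398(two hybrid pooling)", 2), rt), 0.718
  )
  expect_equal(experiment_quality_score("unknown_type", rt), 0)
})

test_that("intero_score is the stated combination and is monotone", {
  expect_equal(intero_score(3, 2, 0.906), 6.906)
  expect_equal(intero_score(1, 1, 0.18), 1.18)
  expect_equal(intero_score(1, 1, 0), 1)
  withr::with_seed(9, {
    for (i in 1:20) {
      ss <- runif(1, 1, 5)
      es <- sample(1:5, 1)
      qs <- runif(1, 0, 2)
      base <- intero_score(ss, es, qs)
      expect_gte(intero_score(ss + 1, es, qs), base)
      expect_gte(intero_score(ss, es + 1, qs), base)
      expect_gte(intero_score(ss, es, qs + 0.1), base)
      expect_gte(base, ss * es)
    }
  })
})

test_that("the batch scorer reproduces the one-to-many worked scenario", {
  w <- worked_example_inputs()
  preds <- predict_interologues(w$known, w$ortho, target = "dmel")
  scored <- score_interactions(w$known, preds, w$ortho)
  p <- scored[scored$origin == "predicted", ]
  expect_equal(nrow(p), 1)
  expect_equal(round(p$species_score, 3), 3.501)
  detail <- p$support_scores[[1]]
  expect_equal(
    round(detail$single_species_score[detail$source_species == "hsap"], 3),
    2.501
  )
  expect_equal(
    detail$single_species_score[detail$source_species == "cele"], 1
  )
  # evidence pooled over all four supporting known interactions
  expect_equal(p$experiment_score, 4L)
  expect_equal(p$intero_score, p$species_score * 4)
})

test_that("known interactions receive the home-species contribution", {
  # an unconserved known interaction with one experiment of quality 0.27
  known <- known_table("dmel", "fly1", "fly2")
  rt <- tibble::tibble(
    experiment_type = "MI:0018(two hybrid)", ratio = 0.27
  )
  scored <- score_interactions(known, NULL, empty_ortho_map(), ratios = rt)
  expect_equal(scored$species_score, 1)
  expect_equal(scored$experiment_score, 1L)
  expect_equal(scored$intero_score, 1.27)
  expect_equal(scored$species_notation, "D")
})

test_that("a prediction from k one2one species with quality-0 evidence scores k*N", {
  sps <- c("hsap", "mmus", "cele")
  ortho <- dplyr::bind_rows(lapply(sps, function(s) {
    dplyr::bind_rows(
      ortho_rows("dmel_A", "dmel", paste0(s, "_A"), s),
      ortho_rows("dmel_B", "dmel", paste0(s, "_B"), s)
    )
  }))
  known <- known_table(
    sps, paste0(sps, "_A"), paste0(sps, "_B"),
    evidence = lapply(seq_along(sps), function(i) {
      evidence_rec(sprintf("E%d", i))
    })
  )
  preds <- predict_interologues(known, ortho, target = "dmel")
  scored <- score_interactions(known, preds, ortho)
  p <- scored[scored$origin == "predicted", ]
  expect_equal(p$species_score, 3)
  expect_equal(p$experiment_score, 3L)
  expect_equal(p$intero_score, 9) # k species x N experiments, no quality term
})

test_that("score TSV output carries fixed three-decimal formatting", {
  w <- worked_example_inputs()
  preds <- predict_interologues(w$known, w$ortho, target = "dmel")
  scored <- score_interactions(w$known, preds, w$ortho)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(scored, f)
  out <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(out), nrow(scored))
  raw <- readLines(f)
  expect_true(any(grepl("\t3\\.501\t", raw)))
})
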