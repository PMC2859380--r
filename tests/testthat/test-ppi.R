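write_ppi_file <- function(rows, path) {
  readr::write_tsv(rows, path)
  path
}

pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b))

test_that("read_ppi filters taxon mismatches and non-protein rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_file(tibble::tibble(
    interactor_a = c("h1", "h2", "h3", "h4", "h5"),
    interactor_b = c("h9", "h8", "h7", "h6", "h5"),
    taxid_a = c(9606, 9606, 10090, 9606, 9606),
    taxid_b = c(9606, 9606, 9606, 9606, 9606),
    experiment_type = "MI:0018(two hybrid)",
    evidence_id = sprintf("E%d", 1:5),
    source_db = "intactdb",
    molecule_type_a = c("protein", "rna", "protein", "protein", "protein"),
    molecule_type_b = "protein"
  ), f)
  suppressMessages(rows <- read_ppi(f, "intactdb", "hsap"))
  expect_equal(nrow(rows), 3) # drops the mouse-taxon and the RNA row
  rep <- rejection_report(rows)
  expect_equal(unname(rep[["dropped_taxon_mismatch"]]), 1)
  expect_equal(unname(rep[["dropped_non_protein"]]), 1)
  expect_error(
    read_ppi(f, "intactdb", "unknown_species"),
    "not in the registry"
  )
})

test_that("BIND-style files without experiment columns get the sentinel", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_file(tibble::tibble(
    interactor_a = c("y1", "y2"), interactor_b = c("y3", "y4"),
    taxid_a = 4932, taxid_b = 4932
  ), f)
  rows <- read_ppi(f, "binddb", "scer")
  expect_true(all(rows$experiment_type == "protein_protein"))
  expect_equal(length(unique(rows$evidence_id)), 2)
  merged <- merge_interactomes(rows)
  expect_true(all(merged$n_evidence == 1))
})

test_that("merging dedupes pairs and evidence across databases", {
  db1 <- tibble::tibble(
    interactor_a = "A", interactor_b = "B", species = "hsap",
    experiment_type = "MI:0018(two hybrid)", evidence_id = "E1",
    source_db = "intactdb"
  )
  db2 <- tibble::tibble(
    interactor_a = "B", interactor_b = "A", species = "hsap",
    experiment_type = "MI:0018(two hybrid)", evidence_id = "E1",
    source_db = "dipdb"
  )
  merged <- merge_interactomes(list(db1, db2))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$gene_a, "A")
  expect_equal(merged$n_evidence, 1) # same experiment counted once
  expect_equal(merged$evidence[[1]]$source_db, "dipdb,intactdb")
})

test_that("merge is order-invariant and bounded by the input union", {
  fx <- generate_fixture(fixture_spec(n_genes = 25, n_conserved = 4, n_predictable = 4, seed = 21), outdir = NULL)
  rows <- fx$data$ppi_rows
  rows$interactor_a <- sub("^(SYN_|OLD_)", "", rows$interactor_a)
  rows$interactor_b <- sub("^(SYN_|OLD_)", "", rows$interactor_b)
  split_rows <- split(rows, rows$source_db)
  m1 <- merge_interactomes(split_rows)
  m2 <- merge_interactomes(rev(split_rows))
  expect_identical(
    as.data.frame(m1[, c("species", "gene_a", "gene_b")]),
    as.data.frame(m2[, c("species", "gene_a", "gene_b")])
  )
  expect_identical(m1$evidence, m2$evidence)
  per_db <- vapply(split_rows, function(r) {
    nrow(dplyr::distinct(tibble::tibble(
      s = r$species, k = pair_key_test(r$interactor_a, r$interactor_b)
    )))
  }, integer(1))
  expect_lte(nrow(m1), sum(per_db))
  # no duplicate evidence records within any interaction
  for (ev in m1$evidence) {
    expect_equal(anyDuplicated(ev[, c("experiment_type", "evidence_id")]), 0)
  }
})

test_that("overlap statistics match trivial and planted designs", {
  one <- tibble::tibble(
    gene_a = "A", gene_b = "B", source_db = "db1"
  )
  two <- dplyr::mutate(one, source_db = "db2")
  st <- overlap_stats(list(one, two))
  expect_equal(st$pairwise$shared_interactions, 1)
  disj <- overlap_stats(list(
    one,
    tibble::tibble(gene_a = "C", gene_b = "D", source_db = "db2")
  ))
  expect_equal(disj$pairwise$shared_interactions, 0)
  expect_equal(disj$union_interactions, 2)

  fx <- generate_fixture(fixture_spec(n_genes = 30, n_conserved = 5, n_predictable = 5, seed = 31), outdir = NULL)
  rows <- fx$data$ppi_rows
  rows$interactor_a <- sub("^(SYN_|OLD_)", "", rows$interactor_a)
  rows$interactor_b <- sub("^(SYN_|OLD_)", "", rows$interactor_b)
  st <- overlap_stats(rows)
  gt <- fx$ground_truth
  expect_equal(
    st$per_db$n_interactions[order(st$per_db$database)],
    gt$db_counts$n_edges[order(gt$db_counts$database)]
  )
  both <- dplyr::inner_join(
    st$pairwise, gt$db_pairwise,
    by = c("db_x", "db_y")
  )
  expect_equal(both$shared_interactions, both$shared_edges)
})

test_that("interactomes round-trip through the TSV serialization", {
  fx <- generate_fixture(fixture_spec(n_genes = 20, n_conserved = 4, n_predictable = 4, seed = 41), outdir = NULL)
  rows <- fx$data$ppi_rows
  rows$interactor_a <- sub("^(SYN_|OLD_)", "", rows$interactor_a)
  rows$interactor_b <- sub("^(SYN_|OLD_)", "", rows$interactor_b)
  merged <- merge_interactomes(rows)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(merged, f)
  back <- read_interactome(f)
  expect_equal(as.data.frame(back), as.data.frame(merged))
})
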