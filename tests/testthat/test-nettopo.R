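test_that("degree distributions sum to one and match direct tallies", {
  tri <- tibble::tibble(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "a"))
  expect_equal(degree_distribution(tri), tibble::tibble(
    degree = 2L, n_nodes = 3L, p = 1
  ))
  star <- tibble::tibble(gene_a = "h", gene_b = c("x", "y", "z"))
  d <- degree_distribution(star)
  expect_equal(d$p[d$degree == 1], 0.75)
  expect_equal(d$p[d$degree == 3], 0.25)
  el <- generate_scale_free(300, 2.2, seed = 4)
  dd <- degree_distribution(el)
  expect_equal(sum(dd$p), 1)
  tally <- table(table(c(el$gene_a, el$gene_b)))
  expect_equal(dd$n_nodes, as.integer(tally))
})

test_that("power-law fits recover exact and planted exponents", {
  k <- 1:50
  p <- k^-2 / sum(k^-2)
  f <- suppressWarnings(fit_power_law(tibble::tibble(degree = k, p = p)))
  expect_equal(f$exponent, 2, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(round(glance(f)$exponent, 6), round(f$exponent, 6))
  expect_equal(tidy(f)$estimate[1], f$exponent)

  # uniform distribution: exponent near 0
  fu <- suppressWarnings(
    fit_power_law(tibble::tibble(degree = 1:20, p = rep(1 / 20, 20)))
  )
  expect_equal(fu$exponent, 0, tolerance = 1e-9)

  expect_error(
    fit_power_law(tibble::tibble(degree = 1:2, p = c(.5, .5))),
    "at least 3"
  )
})

test_that("diameter, clustering and efficiency match brute-force oracles", {
  cases <- list(
    random_edge_table(8, 0.4, 101),
    random_edge_table(15, 0.2, 102),
    random_edge_table(30, 0.1, 103),
    random_edge_table(40, 0.08, 104)
  )
  for (edges in cases) {
    if (nrow(edges) == 0) next
    expect_equal(net_diameter(edges), oracle_diameter(edges))
    expect_equal(clustering_coefficient(edges), oracle_clustering(edges))
    expect_equal(global_efficiency(edges), oracle_efficiency(edges))
  }
  # hand cases
  path5 <- tibble::tibble(gene_a = letters[1:4], gene_b = letters[2:5])
  expect_equal(net_diameter(path5), 4)
  k4 <- tibble::tibble(
    gene_a = c("a", "a", "a", "b", "b", "c"),
    gene_b = c("b", "c", "d", "c", "d", "d")
  )
  expect_equal(net_diameter(k4), 1)
  expect_equal(clustering_coefficient(k4), 1) # tri = 4, triples = 12
  path3 <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"))
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)
  expect_equal(global_efficiency(path3, c("A", "C")), 0.5)
  # edgeless pair inside a larger network contributes zero
  expect_equal(
    global_efficiency(path3, node_set = c("A", "zz")), 0
  )
  star <- tibble::tibble(gene_a = "h", gene_b = c("x", "y", "z"))
  expect_equal(clustering_coefficient(star), 0)
  single <- tibble::tibble(gene_a = "A", gene_b = "B")
  expect_message(cc0 <- clustering_coefficient(single), "no connected triple")
  expect_equal(cc0, 0)
})

test_that("efficiency is monotone nondecreasing under edge addition", {
  withr::with_seed(13, {
    edges <- random_edge_table(20, 0.15, 77)
    base <- global_efficiency(edges)
    nodes <- unique(c(edges$gene_a, edges$gene_b))
    for (i in 1:10) {
      cand <- sort(sample(nodes, 2))
      more <- dplyr::distinct(dplyr::bind_rows(
        edges, tibble::tibble(gene_a = cand[1], gene_b = cand[2])
      ))
      expect_gte(global_efficiency(more), base)
      edges <- more
      base <- global_efficiency(edges)
    }
  })
})

test_that("rewiring preserves the degree multiset and is seed-deterministic", {
  el <- generate_scale_free(200, 2.3, seed = 5)
  rw1 <- rewire_edges(el, seed = 99)
  rw2 <- rewire_edges(el, seed = 99)
  expect_identical(rw1, rw2)
  expect_false(identical(rw1, rewire_edges(el, seed = 100)))
  deg <- function(e) sort(table(c(e$gene_a, e$gene_b)))
  expect_equal(as.vector(deg(el)), as.vector(deg(rw1)))
  expect_equal(sort(names(deg(el))), sort(names(deg(rw1))))
  # no duplicates or self-loops introduced
  expect_equal(anyDuplicated(paste(rw1$gene_a, rw1$gene_b)), 0)
  expect_false(any(rw1$gene_a == rw1$gene_b))
})

test_that("rewiring dissolves planted triangles", {
  # clustered fixture: disjoint triangles plus a sparse random background
  tri_nodes <- sprintf("t%03d", 1:150)
  tris <- do.call(rbind, lapply(seq(1, 148, by = 3), function(i) {
    tibble::tibble(
      gene_a = tri_nodes[c(i, i + 1, i)],
      gene_b = tri_nodes[c(i + 1, i + 2, i + 2)]
    )
  }))
  back <- random_edge_table(50, 0.05, 7)
  edges <- dplyr::bind_rows(tris, back)
  before <- clustering_coefficient(edges)
  lower <- vapply(1:20, function(s) {
    clustering_coefficient(rewire_edges(edges, seed = s)) < before
  }, logical(1))
  expect_gte(sum(lower), 19)
})

test_that("partial rewiring keeps known edges verbatim", {
  nets <- modular_networks(n = 120, n_mod = 6, seed = 3,
    known_per_mod = 15, cross = 60, pred_per_mod = 8
  )
  out <- rewire_predicted(nets$known, nets$predicted, seed = 12)
  kept <- out[out$origin == "known", c("gene_a", "gene_b")]
  expect_setequal(
    paste(kept$gene_a, kept$gene_b),
    paste(
      pmin(nets$known$gene_a, nets$known$gene_b),
      pmax(nets$known$gene_a, nets$known$gene_b)
    )
  )
  # predicted degree sequence preserved
  deg <- function(e) sort(table(c(e$gene_a, e$gene_b)))
  pred_out <- out[out$origin == "predicted", ]
  expect_equal(
    as.vector(deg(nets$predicted)), as.vector(deg(pred_out))
  )
  # no rewired predicted edge duplicates a known edge
  expect_equal(
    length(intersect(
      paste(pred_out$gene_a, pred_out$gene_b),
      paste(kept$gene_a, kept$gene_b)
    )), 0
  )
  # zero predicted edges: identity
  id <- rewire_predicted(nets$known, nets$predicted[0, ], seed = 1)
  expect_equal(nrow(id), nrow(kept))
})

test_that("uniform randomization keeps nodes and edge count", {
  el <- generate_scale_free(100, 2.5, seed = 8)
  rnd <- randomize_edges(el, seed = 5)
  expect_equal(nrow(rnd), nrow(el))
  expect_true(all(c(rnd$gene_a, rnd$gene_b) %in% c(el$gene_a, el$gene_b)))
  expect_equal(anyDuplicated(paste(rnd$gene_a, rnd$gene_b)), 0)
  # on a large dense fixture the clustering approaches the edge density
  big <- random_edge_table(40, 0.5, 21)
  r2 <- randomize_edges(big, seed = 31)
  dens <- nrow(big) / choose(40, 2)
  expect_equal(clustering_coefficient(r2), dens, tolerance = 0.25)
})

test_that("node-set efficiency z-scores flag enrichment and calibrate", {
  # planted dense module in a sparse background
  withr::with_seed(77, {
    back <- random_edge_table(60, 0.03, 55)
    mod_nodes <- sprintf("v%02d", 1:8)
    clique <- t(combn(mod_nodes, 2))
    edges <- dplyr::distinct(dplyr::bind_rows(
      back, tibble::tibble(gene_a = clique[, 1], gene_b = clique[, 2])
    ))
    z <- efficiency_zscore(edges, mod_nodes, n_samples = 500, seed = 42)
    expect_gt(z$z, 3)
    expect_lt(z$p_normal, 0.01)
    g <- glance(z)
    expect_equal(g$observed, z$observed)

    # random node sets are not flagged
    nodes <- unique(c(edges$gene_a, edges$gene_b))
    zs <- vapply(1:20, function(i) {
      efficiency_zscore(edges, sample(nodes, 8),
        n_samples = 200, seed = i
      )$z
    }, numeric(1))
    expect_gte(mean(abs(zs) < 3), 0.95)
  })
})

test_that("the whole-network node set gives z = 0 exactly", {
  el <- random_edge_table(12, 0.3, 9)
  nodes <- unique(c(el$gene_a, el$gene_b))
  z <- efficiency_zscore(el, nodes, n_samples = 50, seed = 2)
  expect_identical(z$z, 0)
  expect_false(z$degenerate)
})

test_that("the proportion test matches its closed form", {
  flat <- proportion_test(75, 300, 0.25)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  t10 <- proportion_test(150, 300, 0.25)
  expect_equal(t10$statistic, 10)
  # under-representation gives a negative statistic
  under <- proportion_test(30, 300, 0.25)
  expect_lt(under$statistic, 0)
  # cross-check order of magnitude against the chi-square version
  ct <- suppressWarnings(stats::prop.test(150, 300, p = 0.25, correct = FALSE))
  expect_equal(t10$statistic^2, unname(ct$statistic))
  expect_error(proportion_test(1, 10, 1), "strictly inside")
})
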