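# Brute-force oracles, written independently of the package internals:
# adjacency-matrix Floyd-Warshall distances, direct triangle/triple
# enumeration, and exhaustive interolog enumeration by nested loops.

oracle_adjacency <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  A <- matrix(FALSE, length(nodes), length(nodes),
    dimnames = list(nodes, nodes)
  )
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]
    b <- edges$gene_b[i]
    if (a == b) next # simple-graph convention
    A[a, b] <- TRUE
    A[b, a] <- TRUE
  }
  A
}

oracle_distances <- function(edges) {
  A <- oracle_adjacency(edges)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_diameter <- function(edges) {
  D <- oracle_distances(edges)
  # largest connected component = most members with finite distance
  comp_sizes <- rowSums(is.finite(D))
  members <- which(comp_sizes == max(comp_sizes))
  in_lcc <- is.finite(D[members[1], ])
  max(D[in_lcc, in_lcc])
}

oracle_clustering <- function(edges) {
  A <- oracle_adjacency(edges)
  n <- nrow(A)
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  if (triples == 0) {
    return(0)
  }
  tri <- 0
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 1, n - 1)) {
      if (!A[i, j]) next
      for (k in seq(j + 1, n)) {
        if (A[i, k] && A[j, k]) tri <- tri + 1
      }
    }
  }
  3 * tri / triples
}

oracle_efficiency <- function(edges, node_set = NULL) {
  D <- oracle_distances(edges)
  node_set <- if (is.null(node_set)) rownames(D) else unique(node_set)
  total <- 0
  n <- length(node_set)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      u <- node_set[i]
      v <- node_set[j]
      d <- if (u %in% rownames(D) && v %in% rownames(D)) D[u, v] else Inf
      if (is.finite(d) && d > 0) total <- total + 1 / d
    }
  }
  total / (n * (n - 1) / 2)
}

# Exhaustive interolog prediction: nested loops over species, known pairs
# and orthologue combinations (orthology records read in both directions).
oracle_predict <- function(known, ortho, target) {
  orth_of <- function(gene, from, to) {
    unique(c(
      ortho$target_gene[ortho$source_gene == gene &
        ortho$source_species == from & ortho$target_species == to],
      ortho$source_gene[ortho$target_gene == gene &
        ortho$target_species == from & ortho$source_species == to]
    ))
  }
  known_keys <- function(sp) {
    k <- known[known$species == sp, ]
    paste(pmin(k$gene_a, k$gene_b), pmax(k$gene_a, k$gene_b))
  }
  kt <- known_keys(target)
  preds <- character()
  for (s in setdiff(unique(known$species), target)) {
    ks <- known[known$species == s, ]
    for (i in seq_len(nrow(ks))) {
      for (oa in orth_of(ks$gene_a[i], s, target)) {
        for (ob in orth_of(ks$gene_b[i], s, target)) {
          if (oa == ob) next
          key <- paste(min(oa, ob), max(oa, ob))
          if (!key %in% kt) preds <- c(preds, key)
        }
      }
    }
  }
  sort(unique(preds))
}

random_edge_table <- function(n, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("v%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    tibble::tibble(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2])
  })
}
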