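#' @title Network topology metrics and null models
#' @description Edge tables in, tibbles (or small result objects) out. All
#'   metrics treat the network as a simple undirected graph: self-interactions
#'   and duplicate edges are removed before any computation.
#' @name nettopo
NULL

# Edge tibble -> simple undirected igraph. Accepts gene_a/gene_b, from/to,
# or the first two columns.
as_interaction_graph <- function(edges) {
  if (inherits(edges, "igraph")) {
    return(igraph::simplify(edges))
  }
  nm <- names(edges)
  cols <- if (all(c("gene_a", "gene_b") %in% nm)) {
    c("gene_a", "gene_b")
  } else if (all(c("from", "to") %in% nm)) {
    c("from", "to")
  } else {
    nm[1:2]
  }
  el <- as.matrix(edges[, cols])
  mode(el) <- "character"
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

graph_to_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  canonical_pair(el[, 1], el[, 2]) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Empirical degree distribution
#'
#' The empirical probability p(k) of each observed node degree; the
#' probabilities sum to 1 over the observed degrees.
#'
#' @param edges Edge tibble (columns `gene_a`, `gene_b`; self-loops and
#'   duplicates ignored) or an igraph object.
#' @return Tibble `degree`, `n_nodes`, `p`.
#' @export
degree_distribution <- function(edges) {
  g <- as_interaction_graph(edges)
  if (igraph::vcount(g) == 0) {
    stop("cannot compute a degree distribution of an empty network", call. = FALSE)
  }
  deg <- igraph::degree(g)
  tab <- table(deg)
  tibble(
    degree = as.integer(names(tab)),
    n_nodes = as.integer(tab),
    p = as.integer(tab) / length(deg)
  )
}

#' Fit a power law p(k) = c k^-r to a degree distribution
#'
#' Least squares on (log k, log p(k)) over the unbinned observed degrees
#' with `k >= k_min` and `p > 0`. By default each degree is weighted by the
#' number of nodes observed at it: the sampling variance of `log p(k)` is
#' approximately inversely proportional to that count, and unweighted
#' fitting lets the noisy single-node tail (whose empirical `p` cannot fall
#' below `1/n`) flatten the slope. Returns the exponent `r` (minus the
#' fitted slope), the prefactor `c` (exponentiated intercept) and the
#' R-squared of the log-log line. At least three distinct degrees are
#' required. Supports [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()].
#'
#' @param distribution A degree-distribution tibble from
#'   [degree_distribution()], or an edge tibble / igraph (the distribution
#'   is computed first).
#' @param k_min Smallest degree included in the fit (default 1; degree-0
#'   nodes never enter, log is undefined there).
#' @param weighted Weight each degree by its node count (default TRUE;
#'   requires the `n_nodes` column, otherwise the fit falls back to
#'   unweighted).
#' @return An object of class `powerlaw_fit`.
#' @export
fit_power_law <- function(distribution, k_min = 1, weighted = TRUE) {
  if (!(is.data.frame(distribution) && all(c("degree", "p") %in% names(distribution)))) {
    distribution <- degree_distribution(distribution)
  }
  d <- distribution[distribution$degree >= k_min & distribution$p > 0, ]
  if (nrow(d) < 3) {
    stop("power-law fit needs at least 3 distinct degrees >= k_min", call. = FALSE)
  }
  w <- if (weighted && "n_nodes" %in% names(d)) d$n_nodes else NULL
  d$.w <- w %||% rep(1, nrow(d))
  fit <- stats::lm(log(p) ~ log(degree), data = d, weights = d$.w)
  r2 <- summary(fit)$r.squared
  structure(
    list(
      exponent = -unname(stats::coef(fit)[2]),
      prefactor = exp(unname(stats::coef(fit)[1])),
      r_squared = r2,
      k_range = range(d$degree),
      n_degrees = nrow(d),
      method = if (is.null(w)) "ols_loglog" else "wls_loglog",
      distribution = distribution
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit p(k) = c k^-r (OLS, log-log)\n  r = %.4f, c = %.4g, R^2 = %.4f\n  %d degrees in [%d, %d]\n",
    x$exponent, x$prefactor, x$r_squared, x$n_degrees,
    x$k_range[1], x$k_range[2]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_power_law
#' @param x A `powerlaw_fit` object.
#' @param ... Unused.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(
    term = c("exponent", "prefactor"),
    estimate = c(x$exponent, x$prefactor)
  )
}

#' @rdname fit_power_law
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(
    exponent = x$exponent, prefactor = x$prefactor,
    r.squared = x$r_squared, n_degrees = x$n_degrees,
    k_min = x$k_range[1], k_max = x$k_range[2]
  )
}

#' Network diameter
#'
#' The maximum shortest-path length (in edges) between any two nodes,
#' computed on the largest connected component via breadth-first search.
#'
#' @param edges Edge tibble or igraph.
#' @return Integer diameter.
#' @export
net_diameter <- function(edges) {
  g <- as_interaction_graph(edges)
  if (igraph::ecount(g) == 0) {
    stop("diameter is undefined for an edgeless network", call. = FALSE)
  }
  comp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize))
  )
  as.integer(igraph::diameter(lcc, unconnected = FALSE))
}

#' Global clustering coefficient (transitivity)
#'
#' The global coefficient `c = 3 * triangles / connected triples`, where a
#' connected triple is a path of three nodes. A triangle-free network scores
#' 0; a network without any connected triple scores 0 by convention (with a
#' message). This is the transitivity formula, not the mean local
#' coefficient.
#'
#' @param edges Edge tibble or igraph.
#' @return Dimensionless value in `[0, 1]`.
#' @export
clustering_coefficient <- function(edges) {
  g <- as_interaction_graph(edges)
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc)) {
    message("network has no connected triple; clustering coefficient set to 0")
    return(0)
  }
  cc
}

#' Global efficiency
#'
#' The mean of the reciprocal shortest-path distances over all unordered
#' node pairs: 1 for a complete graph, 0 contributions from disconnected
#' pairs. When `node_set` is given, the mean runs over pairs within that
#' subset but the distances are still computed in the full network, so a
#' sparse subset embedded in a well-connected network can score well.
#'
#' @param edges Edge tibble or igraph (the full background network).
#' @param node_set Optional character vector of node names (>= 2); defaults
#'   to all nodes. Names absent from the network count as disconnected.
#' @return Dimensionless value in `[0, 1]`.
#' @export
global_efficiency <- function(edges, node_set = NULL) {
  g <- as_interaction_graph(edges)
  nodes <- igraph::V(g)$name
  node_set <- node_set %||% nodes
  node_set <- unique(node_set)
  if (length(node_set) < 2) {
    stop("global efficiency needs at least 2 nodes", call. = FALSE)
  }
  missing <- setdiff(node_set, nodes)
  present <- intersect(node_set, nodes)
  n <- length(node_set)
  n_pairs <- n * (n - 1) / 2
  if (length(present) < 2) {
    return(0)
  }
  d <- igraph::distances(g, v = present, to = present)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  # pairs touching nodes outside the network contribute 0
  sum(inv) / n_pairs
}

#' Degree-preserving rewiring (full network)
#'
#' Randomizes a network by repeated double-edge swaps: every node keeps its
#' exact degree, and swaps that would create a self-loop or duplicate edge
#' are rejected. Deterministic under a fixed `seed`.
#'
#' @param edges Edge tibble or igraph.
#' @param n_swaps Number of swap attempts (default `10 * |E|`).
#' @param seed Optional integer seed.
#' @return A rewired edge tibble (canonical pairs, sorted).
#' @export
rewire_edges <- function(edges, n_swaps = NULL, seed = NULL) {
  g <- as_interaction_graph(edges)
  n_swaps <- n_swaps %||% (10 * igraph::ecount(g))
  do_rewire <- function() {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  }
  rg <- if (is.null(seed)) do_rewire() else withr::with_seed(seed, do_rewire())
  graph_to_edges(rg)
}

#' Partial rewiring: randomize predicted edges, keep known edges fixed
#'
#' The predicted edges are degree-preservingly rewired among themselves and
#' unioned with the untouched known edges. Rewired predicted edges that
#' collide with a known edge are re-drawn by further targeted swaps; if a
#' collision cannot be resolved within the attempt budget it is kept and a
#' warning is issued (the union then merges it). Zero predicted edges return
#' the known network unchanged.
#'
#' @param known_edges,predicted_edges Edge tibbles.
#' @param n_swaps Swap attempts for the predicted subnetwork
#'   (default `10 * |E_pred|`).
#' @param seed Optional integer seed.
#' @return Combined edge tibble with an `origin` column (`known` edges
#'   verbatim, `predicted` edges rewired).
#' @export
rewire_predicted <- function(known_edges, predicted_edges,
                             n_swaps = NULL, seed = NULL) {
  known <- graph_to_edges(as_interaction_graph(known_edges))
  if (is.null(predicted_edges) || nrow(predicted_edges) == 0) {
    return(dplyr::mutate(known, origin = "known"))
  }
  run <- function() {
    pred <- rewire_edges(predicted_edges, n_swaps = n_swaps)
    resolve_collisions(pred, known)
  }
  pred <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  dplyr::bind_rows(
    dplyr::mutate(known, origin = "known"),
    dplyr::mutate(pred, origin = "predicted")
  )
}

# Re-draw predicted edges that coincide with known edges via double-edge
# swaps constrained to avoid known edges, self-loops and duplicates.
resolve_collisions <- function(pred, known, max_rounds = 200) {
  known_keys <- pair_key(known$gene_a, known$gene_b)
  for (round in seq_len(max_rounds)) {
    keys <- pair_key(pred$gene_a, pred$gene_b)
    bad <- which(keys %in% known_keys)
    if (length(bad) == 0) {
      return(pred)
    }
    for (i in bad) {
      j <- sample.int(nrow(pred), 1)
      if (i == j) next
      u <- pred$gene_a[i]
      v <- pred$gene_b[i]
      x <- pred$gene_a[j]
      y <- pred$gene_b[j]
      # propose (u,x),(v,y); fall back to (u,y),(v,x)
      for (prop in list(c(u, x, v, y), c(u, y, v, x))) {
        e1 <- pair_key(prop[1], prop[2])
        e2 <- pair_key(prop[3], prop[4])
        keys_now <- pair_key(pred$gene_a, pred$gene_b)
        ok <- prop[1] != prop[2] && prop[3] != prop[4] && e1 != e2 &&
          !e1 %in% known_keys && !e2 %in% known_keys &&
          !e1 %in% keys_now[-c(i, j)] && !e2 %in% keys_now[-c(i, j)]
        if (ok) {
          pred[i, c("gene_a", "gene_b")] <- as.list(sort(prop[1:2]))
          pred[j, c("gene_a", "gene_b")] <- as.list(sort(prop[3:4]))
          break
        }
      }
    }
  }
  n_left <- sum(pair_key(pred$gene_a, pred$gene_b) %in% known_keys)
  if (n_left > 0) {
    warning(sprintf(
      "%d predicted edge(s) still collide with known edges after rewiring",
      n_left
    ), call. = FALSE)
  }
  pred
}

#' Uniformly random network on the same nodes
#'
#' Keeps the node set and the edge count, drawing the edges uniformly at
#' random without self-loops or duplicates (an Erdos-Renyi G(n, m) graph on
#' the original nodes).
#'
#' @param edges Edge tibble or igraph.
#' @param seed Optional integer seed.
#' @return A randomized edge tibble.
#' @export
randomize_edges <- function(edges, seed = NULL) {
  g <- as_interaction_graph(edges)
  nodes <- igraph::V(g)$name
  m <- igraph::ecount(g)
  draw <- function() {
    rg <- igraph::sample_gnm(length(nodes), m, directed = FALSE)
    igraph::V(rg)$name <- nodes
    graph_to_edges(rg)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Connectivity Z-score of a node set
#'
#' Measures whether a set of nodes is better connected (by global
#' efficiency, distances in the full network) than random node sets of the
#' same size drawn from the same network. Reports the observed efficiency,
#' the null mean and standard deviation, `z = (obs - mean)/sd`, the
#' normal-tail p-value and an empirical p-value. With
#' `null = "rewired"` the null instead re-measures the same node set in
#' degree-preservingly rewired networks.
#'
#' When the null has zero spread, `z` is 0 if the observed value equals the
#' null value (e.g. the node set is the whole network) and `NA` (flagged
#' `degenerate`) otherwise.
#'
#' @param edges Edge tibble or igraph (full network).
#' @param node_set Character vector of node names (at most all nodes).
#' @param n_samples Number of null samples (default 1000).
#' @param seed Optional integer seed.
#' @param null `"node_sets"` (default: random equally sized node sets) or
#'   `"rewired"` (efficiency of `node_set` in rewired networks).
#' @param two_sided Two-sided normal p-value? Default FALSE (upper tail).
#' @return An object of class `efficiency_zscore` (supports
#'   [generics::glance()] and [ggplot2::autoplot()]).
#' @export
efficiency_zscore <- function(edges, node_set, n_samples = 1000, seed = NULL,
                              null = c("node_sets", "rewired"),
                              two_sided = FALSE) {
  null <- match.arg(null)
  g <- as_interaction_graph(edges)
  nodes <- igraph::V(g)$name
  node_set <- unique(node_set)
  if (length(node_set) > length(nodes)) {
    stop("node_set is larger than the network", call. = FALSE)
  }
  obs <- global_efficiency(g, node_set)
  k <- length(node_set)
  draw_null <- function() {
    vapply(seq_len(n_samples), function(i) {
      if (null == "node_sets") {
        global_efficiency(g, sample(nodes, k))
      } else {
        global_efficiency(rewire_edges(g), node_set)
      }
    }, numeric(1))
  }
  nulls <- if (is.null(seed)) draw_null() else withr::with_seed(seed, draw_null())

  mu <- mean(nulls)
  sd_null <- stats::sd(nulls)
  degenerate <- FALSE
  if (sd_null == 0 || is.na(sd_null)) {
    z <- if (isTRUE(all.equal(obs, mu))) 0 else NA_real_
    degenerate <- is.na(z)
  } else {
    z <- (obs - mu) / sd_null
  }
  p_normal <- if (is.na(z)) {
    NA_real_
  } else if (two_sided) {
    2 * stats::pnorm(-abs(z))
  } else {
    stats::pnorm(-z)
  }
  p_empirical <- (1 + sum(nulls >= obs)) / (n_samples + 1)
  structure(
    list(
      observed = obs, z = z, p_normal = p_normal,
      p_empirical = p_empirical, null_mean = mu, null_sd = sd_null,
      null_efficiencies = nulls, n_samples = n_samples,
      set_size = k, null = null, two_sided = two_sided,
      degenerate = degenerate
    ),
    class = "efficiency_zscore"
  )
}

#' @export
print.efficiency_zscore <- function(x, ...) {
  cat(sprintf(
    "Node-set efficiency: observed %.4f vs null %.4f +/- %.4f (%s)\n  z = %s, p_normal = %s, p_empirical = %.3g (%d samples, set size %d)\n",
    x$observed, x$null_mean, x$null_sd, x$null,
    ifelse(is.na(x$z), "NA (degenerate null)", sprintf("%.2f", x$z)),
    ifelse(is.na(x$p_normal), "NA", sprintf("%.3g", x$p_normal)),
    x$p_empirical, x$n_samples, x$set_size
  ))
  invisible(x)
}

#' @rdname efficiency_zscore
#' @param x An `efficiency_zscore` object.
#' @param ... Unused.
#' @export
glance.efficiency_zscore <- function(x, ...) {
  tibble(
    observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
    z = x$z, p_normal = x$p_normal, p_empirical = x$p_empirical,
    n_samples = x$n_samples, set_size = x$set_size, null = x$null
  )
}

#' One-sample test for a proportion (normal approximation)
#'
#' Tests whether an observed proportion (e.g. the fraction of interactome
#' proteins with orthologues) equals a hypothesized population proportion
#' (the genome-wide fraction), using the one-sample z statistic
#' `(p_hat - p0) / sqrt(p0 (1 - p0) / n)` with a two-sided normal p-value.
#' A negative statistic means the interactome under-represents the genome
#' proportion.
#'
#' @param successes Number of successes observed (e.g. proteins with
#'   orthologues in the interactome).
#' @param n Sample size (>= 1).
#' @param genome_proportion Hypothesized proportion, strictly inside (0, 1).
#' @return A one-row tibble: `estimate`, `null_value`, `statistic`,
#'   `p_value`, `n`.
#' @examples
#' proportion_test(150, 300, 0.25) # statistic 10
#' @export
proportion_test <- function(successes, n, genome_proportion) {
  if (genome_proportion <= 0 || genome_proportion >= 1) {
    stop("genome_proportion must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  p_hat <- successes / n
  stat <- (p_hat - genome_proportion) /
    sqrt(genome_proportion * (1 - genome_proportion) / n)
  tibble(
    estimate = p_hat,
    null_value = genome_proportion,
    statistic = stat,
    p_value = 2 * stats::pnorm(-abs(stat)),
    n = n
  )
}
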