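#' Specify a synthetic multi-species fixture
#'
#' A fixture spec pins down every stochastic choice of the generator:
#' species and genes, the conservation structure (families present in all
#' species, in some, or unique), the orthology-type mix, the identity
#' distribution, per-species known networks with planted modules, planted
#' conserved and predictable interolog pairs, the split of evidence over
#' source databases (the last database uses the BIND-style dialect without
#' experiment annotation and holds only its own edges), the experiment-type
#' alphabet with planted quality ratios, and the seed. Generation is a pure
#' function of the spec: the same spec yields byte-identical files.
#'
#' @param registry Species registry (default: the five standard species).
#' @param n_genes Genes per species (approximate: one-to-many families add
#'   extra paralogues).
#' @param frac_all Fraction of `n_genes` allocated to families conserved in
#'   all species.
#' @param frac_some Fraction allocated to families conserved in a random
#'   subset of species (2 to all-but-one); the remainder is species-unique.
#' @param p_one2many,p_many2many Probability that a conserved family carries
#'   extra paralogues in one (one2many) or two (many2many) species.
#' @param identity_range Uniform range (percent) for orthologue identities.
#' @param n_known_edges Random known interactions per species.
#' @param n_modules,within_module Planted modules per species and the
#'   probability that a random edge falls within a module.
#' @param n_conserved Planted conserved interolog pairs (edge present in two
#'   species).
#' @param n_predictable Planted predictable pairs (edge in a source species,
#'   orthologues but no edge in the target species).
#' @param db_names Database names; the last is written in the BIND-style
#'   dialect.
#' @param db_overlap Probability that a non-BIND edge is also deposited in a
#'   second non-BIND database.
#' @param evidence_types Experiment-type alphabet for annotated databases.
#' @param quality_ratio Named vector of target per-type quality ratios used
#'   to build the reference edge set (the sentinel type `protein_protein`
#'   may be named too).
#' @param evidence_per_edge Integer range (min, max) of evidence records per
#'   annotated edge. The default (1, 1) keeps per-type annotation sets
#'   disjoint so the planted ratios are recovered exactly (up to counting
#'   granularity).
#' @param seed Integer seed.
#' @return A validated object of class `fixture_spec`.
#' @seealso [generate_fixture()]
#' @export
fixture_spec <- function(registry = default_species_registry(),
                         n_genes = 40,
                         frac_all = 0.3,
                         frac_some = 0.3,
                         p_one2many = 0.2,
                         p_many2many = 0.1,
                         identity_range = c(40, 99),
                         n_known_edges = 60,
                         n_modules = 4,
                         within_module = 0.8,
                         n_conserved = 10,
                         n_predictable = 10,
                         db_names = c("intactdb", "dipdb", "binddb"),
                         db_overlap = 0.25,
                         evidence_types = c(
                           "MI:0018(two hybrid)",
                           "MI:0019(coimmunoprecipitation)",
                           "MI:0398(two hybrid pooling)"
                         ),
                         quality_ratio = c(
                           "MI:0018(two hybrid)" = 0.5,
                           "MI:0019(coimmunoprecipitation)" = 0.2,
                           "MI:0398(two hybrid pooling)" = 0.7,
                           "protein_protein" = 0.3
                         ),
                         evidence_per_edge = c(1, 1),
                         seed = 20080828) {
  spec <- list(
    registry = validate_registry(registry), n_genes = n_genes,
    frac_all = frac_all, frac_some = frac_some,
    p_one2many = p_one2many, p_many2many = p_many2many,
    identity_range = identity_range, n_known_edges = n_known_edges,
    n_modules = n_modules, within_module = within_module,
    n_conserved = n_conserved, n_predictable = n_predictable,
    db_names = db_names, db_overlap = db_overlap,
    evidence_types = evidence_types, quality_ratio = quality_ratio,
    evidence_per_edge = evidence_per_edge, seed = as.integer(seed)
  )
  fracs <- c(
    frac_all, frac_some, p_one2many, p_many2many, within_module, db_overlap,
    quality_ratio
  )
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions and probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (frac_all + frac_some > 1) {
    stop("frac_all + frac_some must not exceed 1", call. = FALSE)
  }
  counts <- c(n_genes, n_known_edges, n_modules, n_conserved, n_predictable)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (n_modules > max(1, n_genes)) {
    stop("more modules than genes per species", call. = FALSE)
  }
  if (any(identity_range < 0) || any(identity_range > 100) ||
    identity_range[1] > identity_range[2]) {
    stop("identity_range must be an increasing range within [0, 100]",
      call. = FALSE
    )
  }
  n_all <- round(frac_all * n_genes)
  if (n_conserved + n_predictable > choose(n_all, 2)) {
    stop(sprintf(
      "cannot plant %d interolog pairs from %d fully conserved families",
      n_conserved + n_predictable, n_all
    ), call. = FALSE)
  }
  if (nrow(spec$registry) < 2) {
    stop("the fixture needs at least 2 species", call. = FALSE)
  }
  if (length(db_names) < 1) stop("at least one database", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

#' Generate a complete synthetic fixture
#'
#' Emits every input dialect the package consumes -- orthology TSV, synonym
#' TSV, per-database PPI TSVs (per species; the last database in the
#' BIND-style dialect), a reference edge set, a node-set gene list and a
#' species registry -- together with a ground-truth record of everything
#' that was planted. All randomness flows from `spec$seed`; the same spec
#' produces byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed), or `NULL` to skip
#'   writing and return the in-memory tables only.
#' @return A list: `data` (tibbles `ortho`, `edges`, `ppi_rows`, `synonyms`,
#'   `reference_edges`, `node_set`), `ground_truth` (planted conserved and
#'   predictable pairs, per-database bookkeeping, actual quality ratios),
#'   and `paths` (named file paths, when `outdir` is given).
#' @export
generate_fixture <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, build_fixture(spec, outdir))
}

build_fixture <- function(spec, outdir) {
  reg <- spec$registry
  species <- reg$code
  n_sp <- length(species)

  ## -- gene families ---------------------------------------------------
  n_all <- round(spec$frac_all * spec$n_genes)
  n_some <- round(spec$frac_some * spec$n_genes)
  fam_members <- c(
    lapply(seq_len(n_all), function(i) species),
    lapply(seq_len(n_some), function(i) {
      sort(sample(species, sample(2:max(2, n_sp - 1), 1)))
    })
  )
  fam_class <- vapply(fam_members, function(m) length(m) == n_sp, logical(1))

  # gene table: one gene per member species, plus paralogues for
  # one2many / many2many families
  counter <- stats::setNames(rep(0L, n_sp), species)
  gene_rows <- list()
  new_gene <- function(sp) {
    counter[sp] <<- counter[sp] + 1L
    sprintf("%s_g%03d", sp, counter[sp])
  }
  for (f in seq_along(fam_members)) {
    members <- fam_members[[f]]
    extra_in <- character()
    u <- stats::runif(1)
    if (u < spec$p_many2many && length(members) >= 2) {
      extra_in <- sample(members, 2)
    } else if (u < spec$p_many2many + spec$p_one2many) {
      extra_in <- sample(members, 1)
    }
    for (sp in members) {
      n_here <- 1L + sum(extra_in == sp) * sample(1:2, 1)
      for (k in seq_len(n_here)) {
        gene_rows[[length(gene_rows) + 1L]] <-
          list(gene = new_gene(sp), species = sp, family = f)
      }
    }
  }
  # unique (non-conserved) genes fill each species up to n_genes
  for (sp in species) {
    while (counter[sp] < spec$n_genes) {
      gene_rows[[length(gene_rows) + 1L]] <-
        list(gene = new_gene(sp), species = sp, family = NA_integer_)
    }
  }
  genes <- dplyr::bind_rows(gene_rows)

  ## -- orthology -------------------------------------------------------
  ortho <- make_fixture_orthology(genes, spec)

  ## -- known networks --------------------------------------------------
  genes$module <- NA_integer_
  for (sp in species) {
    idx <- which(genes$species == sp)
    genes$module[idx] <- rep_len(seq_len(spec$n_modules), length(idx))[
      sample(length(idx))
    ]
  }
  edges <- list()
  for (sp in species) {
    sp_genes <- genes[genes$species == sp, ]
    got <- character()
    tries <- 0L
    while (length(got) < spec$n_known_edges && tries < spec$n_known_edges * 50) {
      tries <- tries + 1L
      pool <- if (stats::runif(1) < spec$within_module) {
        m <- sample.int(spec$n_modules, 1)
        sp_genes$gene[sp_genes$module == m]
      } else {
        sp_genes$gene
      }
      if (length(pool) < 2) next
      pair <- sort(sample(pool, 2))
      key <- paste(pair, collapse = "\r")
      if (!key %in% got) got <- c(got, key)
    }
    parts <- strsplit(got, "\r", fixed = TRUE)
    edges[[sp]] <- tibble(
      species = sp,
      gene_a = vapply(parts, `[`, character(1), 1),
      gene_b = vapply(parts, `[`, character(1), 2),
      planted = "random"
    )
  }
  edges <- dplyr::bind_rows(edges)

  ## -- planted interologs ----------------------------------------------
  all_fams <- which(fam_class)
  n_plant <- spec$n_conserved + spec$n_predictable
  fam_pairs <- if (length(all_fams) >= 2) {
    utils::combn(all_fams, 2)
  } else {
    matrix(integer(), nrow = 2)
  }
  picked <- if (n_plant > 0) sample(ncol(fam_pairs), n_plant) else integer()
  rep_gene <- function(f, sp) {
    genes$gene[!is.na(genes$family) & genes$family == f &
      genes$species == sp][1]
  }
  add_edge <- function(edges, sp, g1, g2, tag) {
    pair <- sort(c(g1, g2))
    hit <- edges$species == sp & edges$gene_a == pair[1] &
      edges$gene_b == pair[2]
    if (any(hit)) {
      edges$planted[hit] <- tag
      edges
    } else {
      dplyr::bind_rows(edges, tibble(
        species = sp, gene_a = pair[1], gene_b = pair[2], planted = tag
      ))
    }
  }

  planted_conserved <- list()
  for (k in seq_len(spec$n_conserved)) {
    fp <- fam_pairs[, picked[k]]
    st <- sample(species, 2)
    g <- list(
      a_s = rep_gene(fp[1], st[1]), b_s = rep_gene(fp[2], st[1]),
      a_t = rep_gene(fp[1], st[2]), b_t = rep_gene(fp[2], st[2])
    )
    edges <- add_edge(edges, st[1], g$a_s, g$b_s, "conserved")
    edges <- add_edge(edges, st[2], g$a_t, g$b_t, "conserved")
    planted_conserved[[k]] <- tibble(
      species_1 = st[1], gene_1a = min(g$a_s, g$b_s), gene_1b = max(g$a_s, g$b_s),
      species_2 = st[2], gene_2a = min(g$a_t, g$b_t), gene_2b = max(g$a_t, g$b_t)
    )
  }

  planted_predictable <- list()
  for (k in seq_len(spec$n_predictable)) {
    fp <- fam_pairs[, picked[spec$n_conserved + k]]
    st <- sample(species, 2) # st[1]: source with the edge, st[2]: target
    edges <- add_edge(
      edges, st[1], rep_gene(fp[1], st[1]), rep_gene(fp[2], st[1]),
      "predictable_support"
    )
    # the target species must have no edge between any orthologue pair
    f1_t <- genes$gene[!is.na(genes$family) & genes$family == fp[1] &
      genes$species == st[2]]
    f2_t <- genes$gene[!is.na(genes$family) & genes$family == fp[2] &
      genes$species == st[2]]
    forbidden <- pair_key(
      rep(f1_t, each = length(f2_t)), rep(f2_t, length(f1_t))
    )
    drop <- edges$species == st[2] &
      pair_key(edges$gene_a, edges$gene_b) %in% forbidden
    edges <- edges[!drop, ]
    cand <- tidyr::expand_grid(a = f1_t, b = f2_t) |>
      dplyr::filter(.data$a != .data$b)
    planted_predictable[[k]] <- tibble(
      target_species = st[2],
      gene_a = pmin(cand$a, cand$b), gene_b = pmax(cand$a, cand$b),
      source_species = st[1]
    ) |> dplyr::distinct()
  }

  ## -- evidence and databases ------------------------------------------
  n_db <- length(spec$db_names)
  bind_db <- spec$db_names[n_db]
  open_dbs <- spec$db_names[-n_db]
  edges$edge_id <- seq_len(nrow(edges))
  # BIND-style database holds only its own edges; the annotated databases
  # share edges according to db_overlap
  primary <- sample(spec$db_names, nrow(edges),
    replace = TRUE,
    prob = rep(1, n_db)
  )
  assignment <- lapply(seq_len(nrow(edges)), function(i) {
    dbs <- primary[i]
    if (dbs != bind_db && length(open_dbs) > 1 &&
      stats::runif(1) < spec$db_overlap) {
      dbs <- c(dbs, sample(setdiff(open_dbs, dbs), 1))
    }
    dbs
  })

  ev_counter <- 0L
  evidence <- lapply(seq_len(nrow(edges)), function(i) {
    if (identical(assignment[[i]], bind_db)) {
      return(NULL)
    } # sentinel assigned at read time
    n_ev <- sample(seq(spec$evidence_per_edge[1], spec$evidence_per_edge[2]), 1)
    types <- sample(spec$evidence_types, min(n_ev, length(spec$evidence_types)))
    ids <- sprintf("EXP%05d", ev_counter + seq_along(types))
    ev_counter <<- ev_counter + length(types)
    tibble(edge_id = i, experiment_type = types, evidence_id = ids)
  })
  evidence <- dplyr::bind_rows(evidence)

  ## -- synonyms ---------------------------------------------------------
  synonyms <- dplyr::bind_rows(
    tibble(
      external_id = genes$gene, gene_id = genes$gene,
      species = genes$species,
      status = ifelse(stats::runif(nrow(genes)) < 0.1, "novel", "known")
    ),
    tibble(
      external_id = paste0("SYN_", genes$gene), gene_id = genes$gene,
      species = genes$species, status = "known"
    ),
    tibble(
      external_id = paste0("OLD_", genes$gene), gene_id = genes$gene,
      species = genes$species, status = "retired"
    )
  )
  # a gene's own status must be consistent between its rows
  self_status <- synonyms$status[seq_len(nrow(genes))]

  ## -- PPI file rows ----------------------------------------------------
  alias <- function(g) {
    u <- stats::runif(length(g))
    ifelse(u < 0.10, paste0("SYN_", g), ifelse(u < 0.15, paste0("OLD_", g), g))
  }
  taxid_of <- stats::setNames(reg$taxid, reg$code)
  ppi_rows <- list()
  for (db in spec$db_names) {
    in_db <- vapply(assignment, function(a) db %in% a, logical(1))
    e <- edges[in_db, ]
    if (nrow(e) == 0) next
    if (db == bind_db) {
      rows <- tibble(
        interactor_a = alias(e$gene_a), interactor_b = alias(e$gene_b),
        taxid_a = taxid_of[e$species], taxid_b = taxid_of[e$species],
        species = e$species, source_db = db
      )
    } else {
      rows <- e |>
        dplyr::inner_join(evidence, by = "edge_id") |>
        (\(d) tibble(
          interactor_a = alias(d$gene_a), interactor_b = alias(d$gene_b),
          taxid_a = taxid_of[d$species], taxid_b = taxid_of[d$species],
          experiment_type = d$experiment_type, evidence_id = d$evidence_id,
          species = d$species, source_db = db
        ))()
    }
    ppi_rows[[db]] <- rows
  }
  ppi_rows <- dplyr::bind_rows(ppi_rows)

  ## -- reference edges: plant the quality ratios ------------------------
  edge_types <- dplyr::bind_rows(
    evidence |>
      dplyr::distinct(.data$edge_id, .data$experiment_type),
    tibble(
      edge_id = which(vapply(
        assignment, function(a) identical(a, bind_db), logical(1)
      )),
      experiment_type = "protein_protein"
    )
  )
  ref_ids <- integer()
  truth_ratios <- list()
  for (ty in unique(edge_types$experiment_type)) {
    ann <- unique(edge_types$edge_id[edge_types$experiment_type == ty])
    q <- unname(spec$quality_ratio[ty])
    if (is.na(q) || length(q) == 0) q <- 0
    n_ref <- round(q * length(ann))
    chosen <- if (n_ref > 0) sample(ann, n_ref) else integer()
    ref_ids <- union(ref_ids, chosen)
    truth_ratios[[ty]] <- tibble(
      experiment_type = ty, annotated = length(ann),
      in_reference = n_ref, ratio = n_ref / length(ann)
    )
  }
  # with multi-type evidence the per-type reference picks interact; record
  # the realized ratios, which are exact for single-type specs
  truth_ratios <- dplyr::bind_rows(truth_ratios)
  if (spec$evidence_per_edge[2] > 1) {
    realized <- edge_types |>
      dplyr::mutate(in_ref = .data$edge_id %in% ref_ids) |>
      dplyr::group_by(.data$experiment_type) |>
      dplyr::summarise(
        annotated = dplyr::n(), in_reference = sum(.data$in_ref),
        .groups = "drop"
      ) |>
      dplyr::mutate(ratio = .data$in_reference / .data$annotated)
    truth_ratios <- realized
  }
  reference_edges <- edges[edges$edge_id %in% ref_ids, ] |>
    dplyr::select("gene_a", "gene_b") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)

  ## -- node set ---------------------------------------------------------
  node_set <- genes$gene[genes$species == species[1] & genes$module == 1]

  ## -- bookkeeping ------------------------------------------------------
  db_counts <- tibble(
    database = spec$db_names,
    n_edges = vapply(spec$db_names, function(db) {
      sum(vapply(assignment, function(a) db %in% a, logical(1)))
    }, integer(1))
  )
  db_pairwise <- tidyr::expand_grid(
    db_x = spec$db_names, db_y = spec$db_names
  ) |>
    dplyr::filter(.data$db_x < .data$db_y)
  db_pairwise$shared_edges <- mapply(function(x, y) {
    sum(vapply(assignment, function(a) all(c(x, y) %in% a), logical(1)))
  }, db_pairwise$db_x, db_pairwise$db_y, USE.NAMES = FALSE)

  ground_truth <- list(
    planted_conserved = dplyr::bind_rows(planted_conserved),
    planted_predictable = dplyr::bind_rows(planted_predictable),
    db_counts = db_counts,
    db_pairwise = db_pairwise,
    quality_ratios = truth_ratios,
    n_edges_per_species = edges |> dplyr::count(.data$species, name = "n_edges")
  )

  data <- list(
    genes = as_tibble(genes),
    ortho = ortho,
    edges = dplyr::select(edges, "species", "gene_a", "gene_b", "planted"),
    ppi_rows = ppi_rows,
    synonyms = synonyms,
    self_status = self_status,
    reference_edges = reference_edges,
    node_set = node_set
  )

  paths <- NULL
  if (!is.null(outdir)) {
    paths <- write_fixture_files(data, ground_truth, spec, outdir)
  }
  list(data = data, ground_truth = ground_truth, paths = paths)
}

make_fixture_orthology <- function(genes, spec) {
  fams <- genes[!is.na(genes$family), ]
  out <- list()
  for (f in unique(fams$family)) {
    fg <- fams[fams$family == f, ]
    sps <- unique(fg$species)
    if (length(sps) < 2) next
    for (i in seq_along(sps)) {
      for (j in seq_along(sps)) {
        if (i >= j) next
        s <- sps[i]
        t <- sps[j]
        gs <- fg$gene[fg$species == s]
        gt <- fg$gene[fg$species == t]
        htype <- if (length(gs) == 1 && length(gt) == 1) {
          "one2one"
        } else if (length(gs) == 1 || length(gt) == 1) {
          "one2many"
        } else {
          "many2many"
        }
        grid <- tidyr::expand_grid(g1 = gs, g2 = gt)
        ident <- stats::runif(
          nrow(grid), spec$identity_range[1], spec$identity_range[2]
        )
        ident <- round(ident, 1)
        out[[length(out) + 1L]] <- dplyr::bind_rows(
          tibble(
            source_gene = grid$g1, source_species = s,
            target_gene = grid$g2, target_species = t,
            homology_type = htype, percent_identity = ident
          ),
          tibble(
            source_gene = grid$g2, source_species = t,
            target_gene = grid$g1, target_species = s,
            homology_type = htype, percent_identity = ident
          )
        )
      }
    }
  }
  if (length(out) == 0) {
    return(empty_orthology())
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(
      .data$source_species, .data$target_species,
      .data$source_gene, .data$target_gene
    )
}

write_fixture_files <- function(data, ground_truth, spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  paths <- list()

  paths$orthology <- p("orthology.tsv")
  write_orthology(data$ortho, paths$orthology)

  paths$synonyms <- p("synonyms.tsv")
  readr::write_tsv(
    dplyr::arrange(data$synonyms, .data$external_id),
    paths$synonyms,
    progress = FALSE
  )

  bind_db <- spec$db_names[length(spec$db_names)]
  for (db in unique(data$ppi_rows$source_db)) {
    for (sp in unique(data$ppi_rows$species)) {
      rows <- data$ppi_rows[
        data$ppi_rows$source_db == db & data$ppi_rows$species == sp,
      ]
      if (nrow(rows) == 0) next
      fname <- sprintf("ppi_%s_%s.tsv", db, sp)
      cols <- if (db == bind_db) {
        c("interactor_a", "interactor_b", "taxid_a", "taxid_b")
      } else {
        c(
          "interactor_a", "interactor_b", "taxid_a", "taxid_b",
          "experiment_type", "evidence_id", "source_db"
        )
      }
      readr::write_tsv(
        dplyr::arrange(rows[, cols], .data$interactor_a, .data$interactor_b),
        p(fname),
        progress = FALSE
      )
      paths[[fname]] <- p(fname)
    }
  }

  paths$reference_edges <- p("reference_edges.tsv")
  readr::write_tsv(data$reference_edges, paths$reference_edges,
    progress = FALSE
  )

  paths$node_set <- p("node_set.txt")
  writeLines(sort(data$node_set), paths$node_set)

  paths$registry <- p("registry.yaml")
  write_species_registry(spec$registry, paths$registry)

  paths$ground_truth <- p("groundtruth.json")
  jsonlite::write_json(ground_truth, paths$ground_truth,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths
}

#' Generate a scale-free network (configuration model)
#'
#' Draws a degree sequence from the discrete power law p(k) proportional to
#' k^-exponent on 1..k_max, realizes it with the configuration model, and
#' simplifies the result (self-loops and multi-edges removed, so realized
#' degrees can fall slightly below the drawn ones).
#'
#' @param n Number of nodes (>= 10).
#' @param exponent Power-law exponent of the degree distribution.
#' @param seed Optional integer seed.
#' @param k_max Maximum degree (default `floor(sqrt(n))`).
#' @return An edge tibble (`gene_a`, `gene_b`); the full node name vector
#'   (including any node isolated by simplification) is attached as
#'   attribute `"nodes"`.
#' @export
generate_scale_free <- function(n, exponent = 2.5, seed = NULL, k_max = NULL) {
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  k_max <- k_max %||% max(3L, floor(sqrt(n)))
  draw <- function() {
    ks <- seq_len(k_max)
    deg <- sample(ks, n, replace = TRUE, prob = ks^(-exponent))
    if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + if (deg[1] < k_max) 1L else -1L
    g <- igraph::sample_degseq(deg, method = "configuration")
    igraph::V(g)$name <- sprintf("n%05d", seq_len(n))
    igraph::simplify(g)
  }
  g <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(graph_to_edges(g), nodes = igraph::V(g)$name)
}
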