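Package: interoscore
Title: Cross-Species Protein Interaction Prediction and Confidence Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions (interologs) across species
    from orthology, merges per-database binary interaction tables into
    non-redundant interactomes, and assigns each known and predicted
    interaction a unified confidence measure (the InteroScore, combining
    orthology strength across supporting species, the number of distinct
    supporting experiments, and per-experiment-type quality ratios against a
    reference interaction set). Includes a network-topology validation suite
    (power-law degree-distribution fits, diameter, global clustering
    coefficient, global efficiency, degree-preserving rewiring null models,
    node-set efficiency Z-scores), a seeded multi-species synthetic fixture
    generator, and Cytoscape-compatible SIF/edge-attribute export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
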