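---
title: "Interolog prediction and the InteroScore: model, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interolog prediction and the InteroScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interoscore)
library(dplyr)
```

## The problem and the model

A species' experimentally mapped interactome is sparse: outside budding
yeast, most proteins appear in no recorded interaction at all. Interolog
prediction exploits conservation: if proteins A and B interact in species
*s*, and A and B have orthologues A′ and B′ in species *t* with no recorded
interaction between them, then (A′, B′) is predicted in *t*. `interoscore`
applies this rule over every pair of species in a registry, enumerating the
**full Cartesian product** of A-orthologues × B-orthologues under
one-to-many and many-to-many orthology (minus pairs whose two members are
the same gene). Enumerating beyond the single best orthologue is deliberate:
weaker paralogous support is real evidence, and the scoring model below
weights it by sequence identity instead of discarding it.

Predictions and known interactions are disjoint by construction, and a
candidate supported by several source species or several source
interactions becomes one prediction with all supports attached — the
scoring model needs that bookkeeping.

## The confidence scores

For one protein toward one supporting species, let the contributing
orthologues have percent identities $s_1 \ge s_2 \ge \dots \ge s_n$ and
relative identities $r_i = s_i / s_1$. Then:

* **OrthoScore** $= \sum_i r_i^2$. A one-to-one orthologue scores exactly 1;
  $n$ equally strong orthologues score $n$; weak extra orthologues add
  little because the ratios are squared. *Contributing* means participating
  in at least one supporting known interaction in that species — an
  orthologue that never appears in a supporting interaction neither adds to
  the sum nor sets the identity maximum.
* **SingleSpeciesScore** is the product of the two partners' OrthoScores.
* **SpeciesScore** is the sum of SingleSpeciesScores over all species with
  an observed supporting interaction, plus 1 when the interaction is itself
  experimentally known in its home species. Species where the orthologues
  exist but no interaction is recorded contribute nothing — absence of
  evidence is never penalized.
* **ExperimentScore** $N$ counts the distinct supporting experiments,
  pooled over the interaction and all its supporting interologs. Evidence
  records are deduplicated as (experiment type, evidence identifier) pairs,
  so the same experiment reported by two databases counts once while two
  independent two-hybrid studies count twice. A switch
  (`experiment_count = "types"`) counts distinct experiment *types* instead,
  for users who read "each type counted once" strictly.
* **ExperimentQualityScore** weighs evidence by how reliable each
  experiment type has proven: $q(e)$ is the fraction of interactions
  annotated by type $e$ that also appear in an independent reference
  interaction set, and the score sums $q(e)$ over the distinct types behind
  one interaction. The ratio table is an exchangeable input — computed from
  any reference edge set with `quality_ratios()`, or loaded from TSV — so
  no external database is required.
* **InteroScore** $=$ SpeciesScore $\times N +$ ExperimentQualityScore.
  It is monotone nondecreasing in every component. A low score does not
  mean an interaction is unlikely — most predictions have exactly one
  supporting species because coverage is poor — but a high score means
  substantial independent support.

**SpeciesNotation** encodes the evidence pattern compactly: one genus
letter per registry species (registry order, default `H M D C S`),
uppercase where an (orthologous) interaction is observed, lowercase where
only the orthologues exist, omitted where either partner lacks orthologues.
The home letter of a prediction is lowercase by definition.

### Numerical conventions

Relative identities are reduced to **half-percent resolution, rounded
down** (`floor(r * 200) / 200`) before squaring; identities 92/87/72 give
$r =$ 1, 0.945, 0.780 and OrthoScore $1 + 0.945^2 + 0.780^2 = 2.501$,
matching the convention in which relative identities are quoted as
"94.5%" and "78%". This is the package default because it is the only
uniform reduction that reproduces both quoted relative identities; plain
truncation at the third decimal (`rounding = "truncate3"`, giving 0.782 and
a score of 2.505), half-up rounding (`"round3"`) and no reduction
(`"none"`) are available for sensitivity analysis. Scores are carried at
full precision internally and written at three decimals with half-up
rounding.

The home-species contribution of 1 to the SpeciesScore of known
interactions makes known and predicted scores comparable on one scale: an
unconserved known interaction with a single experiment of quality $q$
scores $1 \times 1 + q$, and a maximally conserved prediction from four
one-to-one species scores at least 4.

Identity direction: each directed orthology record carries the identity of
its source protein; scoring reads the record directed from the scored
species toward the supporting species and falls back to the reciprocal
record when only that direction is present.

## Input handling

Orthology, synonym and PPI tables are fixed TSV dialects (documented in
the readers). Loaders validate rather than trust: out-of-range identities,
unknown species, cross-taxon rows and non-protein interactors are dropped
and *counted* (`rejection_report()`), never fatal. Identifier
normalization maps retired accessions forward to their replacements and
synonyms to current gene identifiers, drops rows resolving to the wrong
species, and is idempotent. BIND-style files without experiment annotation
receive the sentinel evidence type `protein_protein`, so interactions
known only from such a source get ExperimentScore 1. Merging keeps one
interaction per unordered pair with a deduplicated evidence set and is
invariant to database order. Self-interactions are retained and flagged
but excluded from all topology metrics (simple-graph convention).

Paralogy records are not consumed: orthology is an input here, and only
orthologous (speciation-derived) relations feed prediction.

## Topology validation

The suite quantifies whether predictions behave like real biology
(densifying modules) or like noise:

* `degree_distribution()` / `fit_power_law()`: the scale-free check
  $p(k) = c\,k^{-r}$ is fitted by least squares on $(\log k, \log p(k))$
  over the unbinned observed degrees, **weighted by the node count at each
  degree**. The weighting matters: the empirical $p(k)$ of a degree
  observed once cannot fall below $1/n$, so an unweighted fit lets the
  sparse tail flatten the slope (on 5000-node configuration-model graphs
  with planted exponent 2.5, unweighted recovery is ~2.05 versus ~2.44
  weighted). `weighted = FALSE` restores the plain fit.
* `net_diameter()` is computed on the largest connected component (the
  choice is ours; disconnected networks have no finite diameter).
* `clustering_coefficient()` is the **global transitivity**
  $c = 3 \cdot \mathrm{triangles} / \mathrm{connected\ triples}$, not the
  mean local coefficient; a network without a connected triple scores 0 by
  convention, with a message.
* `global_efficiency()` is the mean reciprocal shortest-path distance over
  unordered node pairs, with disconnected pairs contributing 0. When a node
  subset is scored, distances are still measured in the **full** network:
  a functionally coherent gene set embedded in a well-connected interactome
  can then score far above what its induced subgraph would allow, which is
  the quantity of interest for subnetwork analysis.
* Null models: `rewire_edges()` (degree-preserving double-edge swaps,
  default `10 × |E|` attempts, rejecting self-loops and duplicates),
  `rewire_predicted()` (predicted edges rewired among themselves, known
  edges kept verbatim, collisions re-drawn by constrained swaps) and
  `randomize_edges()` (uniform edges on the same nodes). All take an
  explicit seed and are exactly reproducible.
* `efficiency_zscore()` compares a node set's efficiency against
  equally-sized uniform node sets (default, matching how subnetwork
  connectivity is usually benchmarked) or, behind `null = "rewired"`,
  against the same set in rewired networks. Both a normal-tail and an
  empirical p-value are reported; a degenerate null (zero spread) yields
  $z = 0$ when observed equals the null value and a flagged `NA`
  otherwise.
* `proportion_test()` is the one-sample normal-approximation test for a
  proportion, $z = (\hat p - p_0)/\sqrt{p_0(1-p_0)/n}$, two-sided — used
  to ask whether proteins with orthologues are over- or under-represented
  in an interactome relative to the genome.

## The fixture generator

`generate_fixture()` emits every input dialect from a single seeded spec:
gene families conserved in all, some, or one species; directed orthology
records with uniform identities (default 40–99%); per-species known
networks with planted modules; planted conserved and predictable interolog
pairs; three database files with controlled overlap, the last in the
BIND-style dialect holding only its own edges; synonym tables with
synonyms and retired identifiers wired into the PPI files; and a reference
edge set constructed so each experiment type hits a planted quality ratio.
Generation is a pure function of the spec — identical specs give
byte-identical files — and a `groundtruth.json` records everything
planted.

What it emulates is the *combinatorial* structure the method depends on
(conservation tiers, orthology-type mix, database overlap, module-biased
edges); what it does not emulate is real biology: identity values are
uniform rather than bimodal, known networks are module-random rather than
scale-free (scale-free graphs come separately from
`generate_scale_free()`, a configuration model, simplified), and evidence
types are assigned independently of interaction truth. Green tests on
fixtures therefore demonstrate correctness of the bookkeeping and the
directional behavior of the statistics, not predictive accuracy on real
interactomes — the latter depends entirely on the quality of the orthology
and interaction inputs.

Default generator parameters (40 genes/species, 30% fully conserved
families, 60 known edges/species over 4 modules, 25% database overlap)
were chosen once as a plausible miniature of a five-species corpus and are
not tuned to any test.

## Validation design and problem sizes

The test suite checks each metric against independent brute-force oracles
(Floyd–Warshall distances, direct triangle/triple enumeration, exhaustive
nested-loop interolog enumeration) on random graphs up to 40 nodes, exact
degree-multiset preservation under rewiring, and full recovery of all
planted fixture truths. The null-model signature — combining modular
predictions with a small-world known network leaves the diameter
essentially unchanged but the partially rewired control loses most of its
clustering, and the fully rewired control more still — is asserted
directionally over 20 seeds on 500-node, 20-module networks; power-law
recovery uses one 5000-node configuration-model draw. These sizes keep the
whole suite around a minute while leaving each assertion far from its
noise floor.

## Known limitations

* Power-law fitting is regression-based; maximum-likelihood
  (Clauset-style) estimation with a fitted $k_{\min}$ is out of scope,
  and the `method` field on the fit object marks the estimator for future
  extension.
* Evidence identifiers are trusted as given: two `evidence_id`s from one
  publication count as two experiments.
* Whether directed interolog counts (s conserved in t vs t in s) should be
  collapsed for Venn-style summaries is left to the caller;
  `find_conserved()` reports both directions.
* MITAB/PSI-MI XML parsing is not included; real database dumps must be
  projected onto the TSV dialects first.
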