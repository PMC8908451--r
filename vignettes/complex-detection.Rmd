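---
title: "Ensemble detection of protein complexes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble detection of protein complexes: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ComplexFinder)
```

# The model

ComplexFinder treats protein-complex detection as a guided local search on
a weighted PPI network. Its working assumptions are the classical ones for
this problem:

* a complex is a cohesive subgraph, organised as a dense **core** with
  peripheral **attachment** proteins;
* members of one complex tend to be co-expressed, share function and
  subcellular compartment, and sit close together in network topology;
* raw high-throughput interaction data contain false positives, so edges
  should be down-weighted or removed when no evidence channel supports
  them;
* a catalogue of known complexes carries learnable topological signal that
  generalises to unseen complexes in the same network.

The pipeline has five stages: evidence-based edge weighting, core mining
(local seed growth plus per-function Markov clustering), supervised
ensemble training, fitness-guided expand/contract search, and redundancy
filtering. Each stage is exposed as ordinary functions
(`buildWeightedNetwork()`, `mineLocalCores()`, `mineGlobalCores()`,
`fitEnsemble()`, `refineCore()`, `filterRedundant()`), with
`detectComplexes()` as the orchestrator.

## Edge weighting

Each edge weight is the plain arithmetic mean of four similarities
(co-expression, GO-slim overlap, localization Dice, embedding cosine).
Three conventions deserve note:

* **Missing evidence contributes 0 but the divisor stays 4.** A pair with
  no expression data is *not* the same as a pair with contradictory
  expression data, but collapsing both to 0 keeps the weight formula
  literal and monotone in available evidence. The alternative
  (renormalising by the number of available channels) would inflate
  weights in sparsely annotated regions of the network.
* **Zero-variance expression profiles score 0** — the Pearson correlation
  is undefined there and a flat profile carries no co-expression signal.
* **Negative cosines clamp to 0** so the composite stays in [0, 1]; an
  anti-correlated embedding direction is read as "no topological
  affinity", not negative evidence.

Edges whose composite weight is exactly 0 (every channel silent) are
removed as noise. The cutoff is an exact equality, not an epsilon
threshold: any nonzero evidence keeps an edge.

## Node embeddings

Topological similarity uses a node2vec-family embedding authored in the
package: second-order random walks with return/in-out parameters p and q
generate node contexts, and the positive pointwise-mutual-information
(PPMI) co-occurrence matrix is factorized by truncated SVD. PPMI + SVD is
the classical closed-form counterpart of skip-gram with negative sampling,
and it makes the embedding exactly reproducible given the walk seed —
important because the whole pipeline promises byte-identical output for a
fixed seed. Defaults (64 dimensions, 10 walks of length 80 per node,
window 10, p = q = 1) are the conventional node2vec settings; no published
values exist for this task, so they are fixed once in the function
signature. Isolated nodes receive zero vectors with a warning: no walk
visits them.

## Core mining

Seed edges are scored w(v, u) × AWD(NG(v, u)) and only edges strictly
above the mean score enter the queue; equal scores are ordered
lexicographically by endpoint pair so runs are reproducible. Growth admits
a neighbour via *any* current member (not only the seed endpoints), in
lexicographic frontier order, repeating until no neighbour qualifies —
the admission rule is the pair of thresholds: edge weight at least the
network average, ECC strictly above the network average.

Two choices here were genuinely open:

* **The average-edge-weight normalization divides by |V|, not |E|.** The
  quantity is named as an average over edges but printed with a node-count
  denominator; we implement the printed form (with `perEdge = TRUE`
  available). On networks with |E| > |V| the |V| form yields a threshold
  above the typical edge weight, so local cores stay close to their seed
  pair and most growth happens later in the fitness-guided search. The
  method is robust to this because refinement can both add and remove
  members.
* **ECC uses unweighted triangle counts** over the weighted network's
  edge set; the weighted variant is a documented non-goal.

Global cores re-implement the per-functional-group strategy: the subgraph
induced by each GO-slim term's annotated proteins is clustered with Markov
clustering (inflation 2, the standard MCL default), clusters pool across
terms, and pairs with neighbourhood affinity ≥ 0.8 merge by union until
stable. The ontology-DAG level traversal of the original functional
grouping is out of scope; one group per term is the flat equivalent over
the two-column annotation format the package reads.

MCL itself iterates expansion (matrix square) and inflation (elementwise
power 2 + column renormalization) on the self-loop-augmented flow matrix
until the largest entry change falls below 1e-6 (cap 100 iterations, with
a warning on non-convergence); clusters are the connected components of
the converged matrix's support (threshold 1e-8). This attractor-support
extraction always yields a partition of the subgraph's nodes.

## The supervised ensemble

Positives are catalogue complexes intersected with the network's node set,
kept at ≥ 3 mapped members; connectivity is *not* required, because the
cohesion term tolerates missing internal edges and an intersection that
happens to be disconnected still carries label signal. Negatives are
connected subgraphs grown by randomized BFS from random starts, with sizes
resampled from the positive size distribution, rejected whenever their
neighbourhood affinity with any positive reaches 0.2. The default ratio is
5 negatives per positive; the ratio is exposed because detection quality
is reported to be stable for ratios roughly between 5 and 15.

Each cluster maps to a fixed-order 65-entry feature vector; the registry
in `featureRegistry()` is the single source of truth for order and
definitions. Several published feature *names* come without formulas;
their package definitions (documented and flagged in the registry help
page) are: topological-coefficient statistics in the Cytoscape sense,
per-edge min/max degree ratios for "degree correlation", the cohesion
score for "community model", relative changes of density / conductance /
weight density / mean clustering under removal of the maximum- and
minimum-degree node for the eight perturbation features, and the three
leading adjacency eigenvalues. Undefined values (empty sets, zero
denominators, NaN statistics of single-element samples) are imputed 0 so
the length-65, all-finite contract always holds.

The four base learners are ordinary least squares, Bayesian ridge
(evidence-maximization updates of the noise and weight precisions),
a regression tree, and linear-kernel support-vector regression, each with
library-default hyperparameters, fitted on identical data; the ensemble
prediction is their unweighted mean. Labels are 1 for positives, 0 for
negatives, so the regression output reads as a complex-likelihood score;
it is clipped to [0, 1] before entering the fitness product, since linear
models can overshoot the label range. Fitting is seeded and fully
reproducible.

The structural-modularity factor SM = Cohesion/(Cohesion + Coupling)
rewards clusters that are internally heavy and externally light. The √|C|
scaling in the cohesion denominator deliberately relaxes the density
criterion for larger clusters, reflecting that real complexes grow sparser
with size. SM returns 0 when both terms vanish (an isolated, internally
empty cluster).

## Search and filtering

Expansion candidates are the core's direct neighbours that share at least
two members with it, ranked by shared-member count (ties lexicographic),
top ⌈k/2⌉ kept — the half rule is applied after the ≥ 2 filter, and
rounding is up, both unspecified in the source narrative. The expansion
phase runs to its own fixed point before contraction starts, matching the
phase structure as narrated; the boundary is recomputed after every
accepted insertion. Contraction considers inner-boundary members only and
never shrinks a cluster below 3 proteins (the "stop at ≤ 2" rule read as a
size floor). Because every accepted move strictly increases a fitness
bounded by 1, termination is guaranteed; `maxRounds = 50` is a pure safety
stop never reached in practice.

The final filter drops clusters under 3 proteins and resolves pairs with
neighbourhood affinity ≥ 0.8 (configurable) in favour of the higher
fitness, greedily from the top; exact duplicates always collapse.

## Evaluation

The implemented maximum matching ratio follows the one-to-one
maximum-weight bipartite matching definition: the printed per-row-maximum
formula conflicts with the narrative and with the cited origin of the
metric, so matching is the default and the printed form is available as
`mmrMode = "rowmax"`. Zero-denominator conventions (no predictions, zero
overlap) return 0 throughout. Enrichment p-values are hypergeometric upper
tails (computed via the stable `phyper` tail, equivalent to the printed
finite sum), Bonferroni-corrected per complex by the number of terms
tested for that complex — the correction scope is not stated in the
source, and per-complex correction matches the LAGO-style tool the metric
imitates. Note one boundary case: when every network protein carries a
term (F = N), observing all-hits is certain and the upper tail is exactly
1, not 0.

# The synthetic benchmark

`generateBenchmark()` plants core-attachment complexes: near-clique cores
(edge probability 0.9, plus a spanning cycle so connectivity never depends
on lucky draws), 1–3 attachments wired to at least two core members
(probability 0.6 per member), and sparse background (60 proteins, edge
probability 0.02, minimum one interaction each, since edge-list-borne
networks contain no isolated proteins). Complex members share a latent
expression profile with Gaussian noise (sd 0.3 around unit-scale
profiles), two complex-specific GO terms and one compartment; background
proteins get independent profiles and decoy annotations. Planted
complexes use disjoint protein sets, so pairwise neighbourhood affinity is
0 and the separation rule holds by construction. Defaults (8 complexes,
cores of 4–8, 12 time points, seed 7) were chosen once to make recovery
demanding but attainable, and are not tuned afterwards.

What the generator does **not** emulate: scale-free degree sequences,
overlapping or nested complexes, shared attachment proteins, biased
annotation coverage, and dynamic (time-sliced) interactions. Passing the
recovery tests therefore demonstrates that the machinery is implemented
coherently end-to-end — weighting amplifies planted signal, cores seed
inside planted complexes, the ensemble separates them from background, the
search reassembles them — not that the method attains any particular
accuracy on real yeast data, which requires the external benchmark
datasets and catalogues.

# Numerical choices and problem sizes

* All similarity and metric operations are closed-form; the only iterative
  pieces are MCL (tolerance 1e-6), Bayesian ridge (tolerance 1e-3, cap
  300), and the search loop (strict-improvement termination).
* Ties are broken lexicographically everywhere a deterministic order is
  needed (seed queue, growth frontier, boundary ranking, output files).
* The test-suite problem sizes are deliberately small: toy graphs of 3–20
  nodes for formula oracles, a 4-complex/25-background benchmark for
  model-dependent tests, the default 8-complex/60-background benchmark
  (≈ 120 proteins, ≈ 300 interactions) for the end-to-end recovery,
  determinism and monotonicity checks, and 100-seed oracle sweeps for the
  matching metric. These sizes keep every independent oracle (exhaustive
  matching enumeration, exhaustive draw enumeration, brute-force
  rescoring) tractable.

# Known limitations

* Complexes of size ≤ 2 are out of reach by design (the size-3 floor).
* One protein can appear in several output complexes only below the
  redundancy threshold; there is no overlap-aware simultaneous growth.
* The flat two-column GO reader cannot reproduce ontology-level functional
  grouping; global cores use one group per term.
* Weighting assumes evidence files index proteins by the same identifiers
  as the edge list; no identifier mapping is attempted.
* The embedding is retrained per network; embeddings are not transferable
  across networks, and on very small or disconnected networks the
  PPMI spectrum carries limited signal.
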