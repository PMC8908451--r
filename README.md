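# ComplexFinder

Detection of protein complexes in protein–protein interaction (PPI)
networks by an ensemble-learning, core-attachment pipeline.

Protein complexes — groups of proteins that interact at the same time and
place to carry out a cellular function — appear in PPI networks as cohesive
subgraphs, typically organised as a dense *core* plus peripheral
*attachment* proteins. High-throughput interaction data are noisy, and
purely unsupervised detectors capture only a few topological shapes of
complex, while single supervised models generalise poorly. ComplexFinder
addresses both problems: it cleans and reweights the network with multiple
evidence channels, and scores candidate clusters with an *ensemble* of a
trained voting regressor and an analytic structural-modularity term. It is
aimed at computational biologists who have an interaction network, optional
expression/annotation data, and a catalogue of known complexes to learn
from.

## Method

**1. Edge weighting.** Every interaction (X, Y) receives the mean of four
similarities, each in [0, 1]:

- co-expression: (PCC(X, Y) + 1) / 2, the rescaled Pearson correlation of
  expression profiles;
- function: |FS(X) ∩ FS(Y)| / min(|FS(X)|, |FS(Y)|) over GO-slim term sets;
- localization: the Dice coefficient 2 |SL(X) ∩ SL(Y)| / (|SL(X)| + |SL(Y)|)
  over subcellular compartments;
- topology: cosine similarity of node2vec-family graph embeddings
  (biased random walks + PPMI factorization), clamped at 0.

W(X, Y) = (PCC + FS + SL + TSS) / 4; edges of weight exactly 0 are treated
as noise and removed.

**2. Core mining.** Seed edges are ranked by
Score(v, u) = w(v, u) × AWD(NG(v, u)), where AWD is the average weighted
degree of the edge's neighbourhood graph; edges scoring above the mean are
processed in order, each unused seed growing a local core by admitting
neighbours x with w(x, t) ≥ the network average edge weight and edge
clustering coefficient ECC(x, t) = Z(x, t)/min(deg x, deg t) above the
network average. A complementary *global* pass runs Markov clustering
(expansion/inflation on the stochastic flow matrix) inside each GO-slim
functional group and merges clusters with neighbourhood affinity ≥ 0.8.

**3. Ensemble scoring.** Known complexes mapped onto the network (≥ 3
proteins) are positives; connected random neighbourhood subgraphs with the
same size distribution and neighbourhood affinity < 0.2 to every positive
are negatives (5 : 1 by default). Each cluster is represented by 65
topological features (entropies, degree/weight statistics, conductance,
modularity, common-neighbour and topological-coefficient statistics,
node-removal perturbations, leading adjacency eigenvalues). Four base
regressors — OLS, Bayesian ridge, a regression tree, and linear-kernel SVR —
are averaged into a voting score VRC(C), and the final fitness is

Fitness(C) = VRC(C) × SM(C),  SM(C) = Cohesion / (Cohesion + Coupling),

with Cohesion(C) = 2 W_in / (√|C| (|C| − 1)) and Coupling(C) = W_out / |C|.

**4. Search and filtering.** Each core alternates expansion (insert the
outer-boundary protein that maximally and strictly increases fitness;
candidates must share ≥ 2 neighbours with the core, top half kept) and
contraction (remove the inner-boundary protein that strictly increases
fitness, never below 3 proteins) until a fixed point. Complexes smaller
than 3 proteins are dropped and redundant ones (neighbourhood affinity
≥ 0.8) collapse to the highest-fitness representative.

**5. Evaluation.** F-measure, Sn/PPV/ACC, maximum matching ratio (maximum
weight bipartite matching on the affinity matrix), coverage rate, composite
Jaccard, their sum (the total score, 0–5), and per-complex hypergeometric
GO enrichment with Bonferroni correction.

## Worked example

The package ships a synthetic benchmark generator that plants
core-attachment complexes together with consistent expression, GO and
localization tables, so the whole pipeline runs without external data:

```r
library(ComplexFinder)

bench <- generateBenchmark(nComplexes = 4, nBackground = 30, seed = 42)
res   <- detectComplexes(bench$network, bench$evidence,
                         catalogue = bench$truth, seed = 42)
#> [weighting] 117 weighted edges
#> [cores] 11 local + 7 global -> 18 after dedup
#> [training] 4 positives, 20 negatives
#> [search] 15 refined complexes
#> [filter] 4 complexes after redundancy filtering

res$complexes
#> ComplexSet with 4 clusters
#>   size range: 6 - 10  mean: 7.5
#>   score range: 0.73 - 0.891

evaluateComplexes(bench$truth, res$complexes,
                  annotations = bench$evidence@goTerms,
                  universe = igraph::vcount(bench$network))
#> EvalReport
#>   numPredicted 4.0000
#>   precision    1.0000
#>   recall       1.0000
#>   fMeasure     1.0000
#>   ...
#>   totalScore   5.0000
#>   enrichment:  4 of 4 complexes significant
```

All four planted complexes are recovered exactly (total score 5 of 5) and
each is significantly enriched for its planted GO term. On harder defaults
(8 complexes, 60 background proteins) recovery is high but not perfect —
see `scripts/acceptance.R`.

`runPipeline()` drives the same steps from files on disk and writes the
weighted network, cores, complexes, fitness sidecar and a JSON report; a
thin command-line wrapper with `simulate` / `train` / `detect` / `evaluate`
subcommands lives at `inst/cli/ppicomplex.R`.

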