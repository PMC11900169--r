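---
title: "Methods: differential MI co-expression networks and their validation"
author: "micoexdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential MI co-expression networks and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices behind them: what each stage assumes, which parameters matter and
why they default to what they do, what the synthetic generator does and does
not emulate, and where numerical care was needed.

## 1. From counts to networks

### Preprocessing

Counts are filtered by **mean CPM ≥ 1** across samples. The per-sample
alternative ("at least *k* samples above 1 CPM") is available through
`min_samples_over_cpm`; the mean rule is the default because it is the one
most filtering utilities for count data apply, and because it is
condition-blind — filtering happens *before* stratification, so both
condition matrices keep the identical gene universe. That identity matters
downstream: percentile thresholding is a rank cut on the set of gene pairs,
so equal universes guarantee equal edge counts in the two networks and make
edge-set comparisons meaningful.

**TMM factors** come from `edgeR::calcNormFactors()` (trims: 30% on M
values, 5% on A values, precision-weighted mean, factors re-centered to
geometric mean 1). Normalized values are `count / (library_size × factor) ×
1e6`, optionally divided by gene length in kb when lengths are supplied.
Length adjustment is off by default: it cannot change within-gene ranks, and
the MI estimator sees only ranks (see below), so it exists for users who
want length-comparable expression tables rather than for the network.

Normalization is not cosmetic for the network either, even though
equal-frequency discretization is rank-based: raw counts share per-sample
sequencing depth, which induces genuine positive dependence between *all*
gene pairs. During validation the permutation null (which preserves per-gene
marginals but destroys between-gene dependence) sat visibly above its band
on raw counts of genes simulated as independent, and inside the band after
TMM/CPM normalization. Calibration checks therefore run on normalized
matrices, as does the pipeline.

### Discretization and mutual information

MI is estimated with the plug-in (maximum-likelihood) estimator on
discretized expression. Defaults: **equal-frequency binning** with
**⌈n_samples^(1/3)⌉ bins** — the cube-root rule commonly used for MI
network inference; both are configurable. Equal-frequency bins are balanced
rank blocks whose occupancies differ by at most one (remainder samples go to
the lowest bins; ties resolve by stable sample order). A constant gene lands
entirely in bin 0 and contributes MI = 0 with every partner — documented
behaviour, not an error, and such pairs can never reach a high percentile.

MI is reported in nats. Only the *rank order* of pair values matters for
percentile thresholding, so the logarithm base cannot change the network.

The full pairwise matrix is computed by an indicator-matrix identity: for
bin pair (a, b) the joint counts of all gene pairs are one matrix product of
0/1 indicator matrices, so the whole computation is `n_bins²` BLAS calls
plus elementwise `x log x`, blocked over gene chunks. Results are exactly
independent of the blocking (a tested contract).

### Percentile thresholding

Edges are the top `k = ⌊(1 − P/100) · N_pairs⌋` pairs by MI, ties at the
boundary broken lexicographically by gene pair, so the construction is fully
deterministic and the two condition networks always receive identical edge
counts. The smallest retained MI is recorded as the threshold. A small
epsilon is added inside the floor because `1 − P/100` is not exactly
representable in binary floating point for percentiles like 99.99 — without
it `k` can come out one too small.

The default percentile is 99.99, the value appropriate for transcriptome-
scale universes (tens of thousands of genes, hundreds of millions of pairs,
where it keeps roughly one edge per gene). **The percentile must scale with
the universe**: for the 2000-gene validation study the same one-edge-per-
gene ratio corresponds to the 99.9th percentile, and that is what the
package's planted-structure recovery checks use. At 99.99 a 2000-gene
universe keeps only ~200 edges, fragmenting planted modules into many
components; at the matched ratio the map-equation partition recovers the
planted partition with NMI ≈ 0.94–0.96. The `percentileSweep()` table
(nodes, edges, components, largest component, transitivity per percentile)
is the method's own instrument for choosing this cut on real data.

### The permutation null

Each permutation shuffles every gene's sample order independently,
preserving all marginals while destroying between-gene dependence, then
recomputes the MI distribution (on a random subsample of at most 1e5 pairs
when the pair set is larger) and records the percentile value. The
empirical p is the fraction of permutations whose null threshold reaches
the observed one. A second, graph-level null (degree-preserving double-edge
swaps, `rewiringNull()`) serves the topological metrics.

## 2. Topology

Degree, betweenness (unweighted shortest paths, fractional over equal-length
alternatives, unnormalized raw path counts), transitivity (3 × triangles /
connected triples), components and diameter are computed with igraph. On
disconnected graphs the diameter is the maximum finite shortest path — i.e.
the largest component-wise diameter — since thresholded co-expression
networks are practically always disconnected.

The scaling exponent γ is the negated OLS slope of `ln p(k)` on `ln k` over
degrees with non-zero frequency — the straight-line reading of the log-log
histogram. This is deliberately *not* a maximum-likelihood power-law fit:
the two answer different questions and differ numerically (log-log slopes
below 1 are common where MLE exponents would exceed 2).
`fitDegreeDistributions()` provides the ML fits — discrete power-law
(Zipf, k ≥ 1, normalized by the Riemann zeta), Poisson, shifted geometric,
negative binomial, and a normal on log-degree — ranked by AIC. The
log-normal candidate's likelihood includes the Jacobian of the log
transform so that all candidates are compared on the same counting measure;
without that term the log-normal spuriously dominates any AIC contest.

Hub genes and high-betweenness genes are the top decile (`k = ⌈0.10 · n⌉`,
boundary ties included, so the set can exceed the nominal size; with all
scores tied it is the whole gene set). Shared/exclusive percentages are
relative to the union of the two sets (Venn semantics).

## 3. Modules

The two-level **map equation** is
`L(M) = q H(Q) + Σ_m p_m H(P_m)` bits per step, with node visit rates
proportional to degree (strength, when the weighted variant is enabled) and
module exit rates proportional to the inter-module edge mass. The optimizer
is Louvain-shaped but scores every candidate move by the *exact* change in
L: greedy sweeps over nodes in seeded random order (candidate targets:
neighboring modules plus a fresh module), then aggregation of modules into
supernodes and recursion. Descent is strictly monotone; `n_trials` random
restarts are kept and the best L wins. On an exhaustive fixture of connected
graphs up to 7 nodes the optimizer attains the global minimum found by
enumerating all set partitions (Bell(7) = 877). `igraph::cluster_infomap()`
is available behind `delegate = "igraph"`; its partitions are re-scored with
the package's own `mapEquation()` either way.

Two-level (flat) coding was chosen over hierarchical coding because the
analysis this package supports reports flat module counts and compares flat
partitions across conditions.

Partitions are scored by Newman modularity, unweighted by default — edges
are already "significant co-expression" indicators once thresholded, and
the weighted variant remains one switch away. Per-module contributions
`e_c/m − (d_c/2m)²` sum exactly to the global Q (a tested conservation).

**NMI** normalizes the label mutual information by the arithmetic mean of
the label entropies — the convention of the common graph-library comparison
functions — and is computed on the intersection of the node sets (the two
condition networks keep different genes); the dropped-node count is
attached to the result. **Membership similarity** is the Jaccard matrix
between module gene sets with a greedy one-to-one best matching (highest
Jaccard first) and preservation counts at thresholds 1.0 … 0.5. Module ids
are always relabeled in decreasing size order for stable reporting.

## 4. Enrichment

Over-representation uses the upper-tail hypergeometric probability
`P(X ≥ n_overlap)` with BH adjustment across all tested terms, and the dual
cutoff p ≤ 0.05 *and* q ≤ 0.05. The background universe defaults to **all
post-filter genes**, not network nodes: network membership is itself an
outcome of the analysis, and conditioning on it would bias enrichment
toward whatever made genes co-express. (A network-nodes background is one
argument away for users who want the alternative.) Annotations are used
exactly as given in the GMT — no ontology-ancestor propagation — because
the synthetic validation needs exact control over term contents.

Functional similarity between modules is the Jaccard index of their
significantly enriched term *sets*. A semantic-similarity weighting layer
(information-content measures between terms) would slot in before the
Jaccard step but is intentionally not implemented: with set overlap the
quantity is exactly testable against ground truth, and the extension point
is documented rather than half-built. Modules with no enriched terms yield
`NA`, not 0 — "no functional identity" is not "different functional
identity".

## 5. The synthetic generator

`syntheticDesign()` / `generateTwoConditionCounts()` emulate exactly the
statistical structure the inference stages assume:

* **Dependence without linearity.** Genes in a module share a latent
  Gaussian factor (`z = √ρ·F + √(1−ρ)·ε`), and the latent normal is pushed
  through the negative-binomial quantile function. Pairwise dependence on
  the count scale is therefore monotone but non-linear — the regime where
  MI has its advantage over correlation-based inference.
* **Study conditions.** The default design is the package's reference
  study: 2000 genes, ten modules of 50, ρ = 0.8, 150 samples per
  condition, NB means log-uniform on [5, 500], dispersion 0.2, library
  sizes uniform on [5e6, 1.5e7]. These are realistic magnitudes for bulk
  brain RNA-seq after gene-level summarization, and module size/correlation
  are in the range where recovery is expected but not trivial.
* **Planted rearrangement.** Condition B reassigns ⌊0.2·|module|⌋ genes per
  module round-robin to the other modules. Determinism makes the
  cross-condition membership Jaccard computable in closed form: each module
  keeps 40 of its 50 genes and receives 10 others, so every matched pair
  has J = 40/60 = 2/3 — the value the similarity machinery must reproduce.
* **Planted hubs.** A handful of background genes load equally on half of
  the module factors in condition B only, becoming multi-module connectors
  that exist in one network and not the other — the substrate for the
  neighbor-gain analysis.
* **Annotations.** One "true" term per planted module (a random coverage
  fraction of its genes, default 0.8) plus size-matched decoy terms of
  random genes.

What the generator does **not** emulate: batch effects (a pass-through
correction hook exists, and an upstream batch-removal method is outside
this package's scope), clinical covariate structure, gene-length bias,
count outliers and zero inflation beyond NB, and any realistic gene-gene
regulatory asymmetry. Passing the validation suite therefore demonstrates
that the machinery is correct and calibrated under its own model — not that
the model captures every property of cohort RNA-seq.

## 6. Validation strategy and problem sizes

The test suite validates every statistic against an independent
implementation: hand-written BFS/path-enumeration/triangle-counting oracles
for graph metrics, literal codebook evaluation for the map equation,
explicit combinatorial sums for the hypergeometric tail, step-up
enumeration for BH, a literal reimplementation of the weighted
trimmed-mean formula for TMM, and `igraph::modularity()` /
`igraph::compare()` as cross-checks for Q and NMI. Fifty randomized toy
graphs (≤ 10 nodes) and vectors (≤ 12 samples) are checked at 1e-9;
exhaustive map-equation optimality is checked on 48 connected graphs of 3–7
nodes.

Calibration checks use moderate sizes chosen for statistical adequacy: the
permutation-null band check runs 100 permutations on an 80-gene, 40-sample
independence design; the ORA type-I check uses 100 random 100-gene queries
against ~40-gene terms over a 2000-gene universe, a geometry whose exact
test size at p ≤ 0.05 is 0.046 — close enough to nominal that discreteness
does not masquerade as miscalibration. Planted-structure recovery runs the
full reference design (2000 genes, 150 + 150 samples).

## 7. Known limitations

* The plug-in MI estimator is biased upward at small n; since thresholding
  is rank-based, the bias matters only through rank distortions, but very
  small studies (n ≲ 30) will produce unstable networks.
* The greedy optimizer guarantees monotone descent and exhaustive
  optimality has been verified only up to 7 nodes; like every Infomap-style
  heuristic it can in principle return a local minimum on large graphs —
  restarts mitigate, and the codelength is always reported so competing
  partitions can be compared.
* Edge weights (MI values) are carried on the networks but the default
  module/modularity analyses are unweighted; the weighted switches are
  provided untested against ground truth (the generator plants membership,
  not weight structure).
* The enrichment stage tests set over-representation only; it does not
  model inter-term correlation induced by overlapping GMT terms.
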