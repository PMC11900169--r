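# micoexdiff

Differential gene co-expression network analysis with mutual information.

## The problem

Genes act in coordinated transcriptional programs, and disease can rewire
that coordination without necessarily changing mean expression of any single
gene. `micoexdiff` is for researchers who have gene-level RNA-seq counts from
two phenotype groups (e.g. pathology vs. control brain tissue) and want to
ask *how the co-expression architecture differs between the groups*: which
genes are hubs in one condition only, which genes broker information flow,
how much of the edge set is shared, and how genes are redistributed across
co-expression modules.

## The method

For each condition the pipeline:

1. **Preprocesses counts** — filters genes with mean CPM < 1, computes TMM
   (trimmed mean of M-values) scaling factors, normalizes to CPM, and
   stratifies samples by condition.
2. **Infers a network from mutual information.** Expression is discretized
   per gene (equal-frequency bins, `⌈n^(1/3)⌉` bins by default) and the
   plug-in estimator

   *I(X;Y) = Σ p̂(x,y) ln [ p̂(x,y) / (p̂(x) p̂(y)) ]*

   is computed for every gene pair. MI is symmetric and captures non-linear
   dependence, so the resulting network is undirected and makes no claim
   about regulatory direction. Only the top pairs at a high percentile of
   the MI distribution (default 99.99%) become edges; a per-gene permutation
   null certifies that the retained dependence is not random.
3. **Characterizes topology** — degree distributions with a log-log scaling
   exponent γ and maximum-likelihood fits of candidate distributions
   (power-law, Poisson, geometric, negative binomial, lognormal) ranked by
   AIC; a two-sample Kolmogorov–Smirnov test between the conditions' degree
   distributions; transitivity, diameter, component census; the edge Jaccard
   index |E₁∩E₂|/|E₁∪E₂|; top-decile hub genes and high-betweenness genes
   with shared/exclusive comparisons; neighbor gains of condition-specific
   hubs; induced subgraphs; degree-preserving rewiring nulls.
4. **Detects modules with the map equation.** A two-level Infomap-style
   optimizer minimizes the description length of a random walk,
   *L(M) = q H(Q) + Σ_m p_m H(P_m)* (bits/step), by greedy node moves and
   module aggregation with random restarts. Partitions are scored by Newman
   modularity *Q = Σ_c [e_c/m − (d_c/2m)²]* globally and per module, and
   compared across conditions by normalized mutual information and by a
   module-membership Jaccard similarity matrix with greedy best matching.
5. **Quantifies function** — hypergeometric over-representation of gene sets
   and modules against GMT annotations with Benjamini–Hochberg FDR, module
   functional-similarity matrices, and per-term module-representation counts
   between conditions.

Because real cohort data of this kind are controlled-access, the package
ships a **synthetic generator**: a Gaussian-copula, negative-binomial
simulator that plants co-expression modules, condition-specific hub genes
and a controlled round-robin reassignment of genes between modules, plus
matching GMT annotations. Every downstream stage can therefore be validated
against known ground truth.

## Worked example

```r
library(micoexdiff)

design <- syntheticDesign(n_genes = 300, n_samples_a = 60, n_samples_b = 60,
                          modules_a = list(1:40, 41:80, 81:120, 121:160),
                          rearrangement_fraction = 0.2,
                          within_module_rho = 0.8, n_hubs_b = 2, seed = 42)
sim <- generateTwoConditionCounts(design)
sim$truth
#> GroundTruth: 300 genes; 4 planted modules; 32 genes reassigned in B; 2 planted hubs

se  <- makeCountSE(cbind(SummarizedExperiment::assay(sim$counts_a, "counts"),
                         SummarizedExperiment::assay(sim$counts_b, "counts")),
                   condition = rep(c("A", "B"), each = 60))
ann <- generateAnnotations(sim$truth, n_decoy_terms = 5, coverage = 0.8, seed = 1)
cfg <- pipelineConfig(seed = 7, percentile = 99.5, n_trials = 5)
report <- runPipeline(se, annotations = ann, config = cfg)

report$conditions$A[c("n_nodes", "n_edges", "transitivity",
                      "n_modules", "modularity_q")]
#> $n_nodes       98
#> $n_edges       224
#> $transitivity  0.2877 (approx.)
#> $n_modules     12
#> $modularity_q  0.528 (approx.)
report$cross$edge_jaccard
#> [1] 0.01357466
report$cross$nmi
#> [1] 0.4798164
```

Reading the output: both condition networks keep the same number of edges by
construction (the percentile is a rank cut on an identically sized pair
set), so differences in node counts, transitivity and modularity are
structural, not size artifacts. The low edge Jaccard and the cross-condition
NMI of ≈0.48 reflect the planted 20% module rearrangement plus sampling
noise at this small study size — module *membership* diverges while modular
*organization* persists, which is exactly the contrast the pipeline is built
to expose.

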