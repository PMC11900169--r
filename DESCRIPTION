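Package: micoexdiff
Title: Differential Gene Co-Expression Network Analysis with Mutual Information
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds mutual-information gene co-expression networks for two
    phenotype groups from RNA-seq counts and compares their architecture.
    Counts are filtered by CPM, normalized by TMM, stratified by condition,
    discretized, and converted to pairwise mutual-information matrices that
    are thresholded at a high percentile to yield condition-specific
    undirected networks. Networks are compared globally (degree-distribution
    fits, Kolmogorov-Smirnov test, transitivity, diameter, edge Jaccard),
    locally (hub and high-betweenness gene sets, neighbor gains, induced
    subgraphs) and mesoscopically (map-equation community detection, Newman
    modularity, normalized mutual information, module membership and
    functional similarity matrices). Hypergeometric over-representation
    against GMT gene sets with Benjamini-Hochberg correction quantifies the
    functional identity of gene sets and modules. A negative-binomial
    Gaussian-copula simulator with planted modules, hubs and cross-condition
    module rearrangement provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    edgeR,
    SummarizedExperiment,
    S4Vectors,
    Matrix,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression, RNASeq,
    Transcriptomics, Network, Clustering
RoxygenNote: 7.3.3
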