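#' @import methods
#' @importFrom stats setNames
NULL

#' Design of a two-condition synthetic co-expression study
#'
#' Describes a negative-binomial Gaussian-copula simulation with planted
#' co-expression modules, controlled cross-condition module rearrangement and
#' planted hub genes in the second condition. The defaults describe the study
#' conditions used throughout the package's validation: 2000 genes, ten
#' modules of 50 genes, latent within-module correlation 0.8, 150 samples per
#' condition and a 20\% round-robin reassignment of module genes in condition
#' B.
#'
#' @slot nGenes number of genes in the shared universe.
#' @slot nSamplesA,nSamplesB samples per condition.
#' @slot modulesA list of disjoint integer vectors of gene indices; genes not
#'   covered by any module are independent background genes.
#' @slot rearrangementFraction fraction of each module's genes reassigned to a
#'   different module in condition B (deterministic round-robin).
#' @slot withinModuleRho latent Gaussian correlation within a module, in
#'   `[0, 1)`.
#' @slot nHubsB number of background genes that, in condition B only, load on
#'   half the module factors and therefore become highly connected.
#' @slot nbMeanLogRange range (natural-log scale) from which per-gene mean
#'   expression is drawn.
#' @slot nbDispersion negative-binomial dispersion (1/size), common to all
#'   genes.
#' @slot librarySizeRange range of per-sample library sizes; samples are
#'   scaled relative to the mean library size.
#' @slot seed integer seed governing all randomness of the generator.
#' @export
setClass("SyntheticDesign",
  representation(
    nGenes = "integer",
    nSamplesA = "integer",
    nSamplesB = "integer",
    modulesA = "list",
    rearrangementFraction = "numeric",
    withinModuleRho = "numeric",
    nHubsB = "integer",
    nbMeanLogRange = "numeric",
    nbDispersion = "numeric",
    librarySizeRange = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nSamplesA < 4L) msg <- c(msg, "nSamplesA must be >= 4")
  if (object@nSamplesB < 4L) msg <- c(msg, "nSamplesB must be >= 4")
  idx <- unlist(object@modulesA)
  if (length(idx)) {
    if (any(duplicated(idx)))
      msg <- c(msg, "modulesA sets must be pairwise disjoint")
    if (any(idx < 1L | idx > object@nGenes))
      msg <- c(msg, "modulesA indices must lie in the gene universe")
  }
  if (object@rearrangementFraction < 0 || object@rearrangementFraction > 1)
    msg <- c(msg, "rearrangementFraction must lie in [0, 1]")
  if (object@withinModuleRho < 0 || object@withinModuleRho >= 1)
    msg <- c(msg, "withinModuleRho must lie in [0, 1)")
  if (object@nHubsB < 0L) msg <- c(msg, "nHubsB must be >= 0")
  if (length(object@nbMeanLogRange) != 2L ||
      diff(object@nbMeanLogRange) < 0)
    msg <- c(msg, "nbMeanLogRange must be an increasing pair")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange <= 0) ||
      diff(object@librarySizeRange) < 0)
    msg <- c(msg, "librarySizeRange must be an increasing positive pair")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic two-condition study
#'
#' @slot partitionA,partitionB named integer vectors mapping every gene to its
#'   module id (0 = unassigned background).
#' @slot hubGenesB character vector of planted hub gene ids (condition B).
#' @slot design the [SyntheticDesign-class] that produced the data.
#' @export
setClass("GroundTruth",
  representation(
    partitionA = "integer",
    partitionB = "integer",
    hubGenesB = "character",
    design = "SyntheticDesign"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!identical(names(object@partitionA), names(object@partitionB)))
    msg <- c(msg, "partitionA and partitionB must cover the same genes")
  if (!all(object@hubGenesB %in% names(object@partitionB)))
    msg <- c(msg, "hubGenesB must be a subset of the gene universe")
  if (length(msg)) msg else TRUE
})

#' Per-gene discretized expression codes
#'
#' @slot bins integer matrix (genes x samples) of bin codes in
#'   `[0, nBins)`.
#' @slot nBins number of bins.
#' @slot method `"equal_frequency"` or `"equal_width"`.
#' @export
setClass("DiscretizedMatrix",
  representation(bins = "matrix", nBins = "integer", method = "character")
)

setValidity("DiscretizedMatrix", function(object) {
  msg <- character()
  if (!is.integer(object@bins)) msg <- c(msg, "bins must be integer codes")
  if (length(object@bins) &&
      (min(object@bins) < 0L || max(object@bins) >= object@nBins))
    msg <- c(msg, "bin codes must lie in [0, nBins)")
  if (!object@method %in% c("equal_frequency", "equal_width"))
    msg <- c(msg, "method must be equal_frequency or equal_width")
  if (length(msg)) msg else TRUE
})

#' Pairwise mutual information for one condition
#'
#' Stores the symmetric matrix of plug-in mutual-information estimates (nats)
#' between all gene pairs; the diagonal is `NA` (self-information is the
#' marginal entropy and is not a co-expression value).
#'
#' @slot mi symmetric numeric matrix with gene ids as dimnames, `NA` diagonal.
#' @slot nSamples number of samples used.
#' @slot nBins,method discretization provenance.
#' @export
setClass("MIResult",
  representation(mi = "matrix", nSamples = "integer", nBins = "integer",
                 method = "character")
)

setValidity("MIResult", function(object) {
  m <- object@mi
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "mi matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "mi matrix needs identical row/col gene ids")
  off <- m[upper.tri(m)]
  if (length(off) && any(off < -1e-12, na.rm = TRUE))
    msg <- c(msg, "mutual information must be non-negative")
  if (length(msg)) msg else TRUE
})

#' An MI-thresholded co-expression network
#'
#' Undirected simple graph over the genes that retain at least one edge after
#' percentile thresholding of the pairwise MI distribution. Edges carry the MI
#' value as weight.
#'
#' @slot graph an [igraph::igraph] object (undirected, simple).
#' @slot thresholdValue smallest retained MI value (nats).
#' @slot percentile percentile used for thresholding.
#' @export
setClass("CoexNetwork",
  representation(graph = "ANY", thresholdValue = "numeric",
                 percentile = "numeric")
)

setValidity("CoexNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) msg <- c(msg, "graph must be an igraph object")
  else {
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g) || igraph::any_multiple(g))
      msg <- c(msg, "graph must be simple (no loops or multi-edges)")
  }
  if (length(msg)) msg else TRUE
})

#' A module partition of a co-expression network
#'
#' @slot membership named integer vector, gene -> module id; ids are
#'   contiguous 1..nModules, ordered by decreasing module size.
#' @slot nModules number of modules.
#' @slot codelength two-level map-equation description length (bits/step).
#' @slot modularityQ global Newman modularity of the partition.
#' @slot perModuleQ per-module contributions summing to `modularityQ`.
#' @slot nTrials,seed optimizer provenance.
#' @slot method `"infomap-greedy"`, `"igraph-infomap"` or `"fixed"`.
#' @export
setClass("GenePartition",
  representation(membership = "integer", nModules = "integer",
                 codelength = "numeric", modularityQ = "numeric",
                 perModuleQ = "numeric", nTrials = "integer",
                 seed = "integer", method = "character")
)

setValidity("GenePartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by gene id")
  if (length(object@membership) &&
      object@nModules != length(unique(object@membership)))
    msg <- c(msg, "nModules must equal the number of distinct module ids")
  if (length(object@modularityQ) == 1L && !is.na(object@modularityQ) &&
      (object@modularityQ < -1 || object@modularityQ > 1))
    msg <- c(msg, "modularity Q must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Cross-condition module similarity
#'
#' Jaccard similarity between the gene contents of every module pair of two
#' partitions, a greedy one-to-one best matching, and preservation counts (how
#' many matched pairs reach each similarity threshold).
#'
#' @slot jaccard modules-A x modules-B matrix of Jaccard indices.
#' @slot matching data.frame with columns `module_a`, `module_b`, `jaccard`.
#' @slot preservation named integer vector of matched pairs with Jaccard at or
#'   above thresholds 1.0, 0.9, 0.8, 0.7, 0.6, 0.5.
#' @export
setClass("ModuleSimilarity",
  representation(jaccard = "matrix", matching = "data.frame",
                 preservation = "integer")
)

setValidity("ModuleSimilarity", function(object) {
  j <- object@jaccard
  if (length(j) && (min(j) < 0 || max(j) > 1))
    "Jaccard entries must lie in [0, 1]" else TRUE
})

#' Term-to-gene annotation sets (GMT semantics)
#'
#' @slot terms named list of character vectors (term id -> gene ids).
#' @slot descriptions named character vector, parallel to `terms`.
#' @slot universe background gene set used for enrichment.
#' @export
setClass("AnnotationSet",
  representation(terms = "list", descriptions = "character",
                 universe = "character")
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (any(duplicated(names(object@terms))))
    msg <- c(msg, "term ids must be unique")
  if (any(lengths(object@terms) == 0L))
    msg <- c(msg, "every term must annotate at least one gene")
  if (!identical(names(object@terms), names(object@descriptions)))
    msg <- c(msg, "descriptions must be named like terms")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign:", object@nGenes, "genes,",
      length(object@modulesA), "planted modules,",
      object@nSamplesA, "+", object@nSamplesB, "samples\n")
  cat("  rho =", object@withinModuleRho,
      " rearrangement =", object@rearrangementFraction,
      " hubs(B) =", object@nHubsB, " seed =", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  moved <- sum(object@partitionA != object@partitionB)
  cat("GroundTruth:", length(object@partitionA), "genes;",
      length(unique(object@partitionA[object@partitionA > 0])),
      "planted modules;", moved, "genes reassigned in B;",
      length(object@hubGenesB), "planted hubs\n")
})

setMethod("show", "MIResult", function(object) {
  g <- nrow(object@mi)
  cat("MIResult:", g, "genes,", g * (g - 1) / 2, "pairs;",
      object@nBins, "bins (", object@method, "),",
      object@nSamples, "samples\n")
})

setMethod("show", "CoexNetwork", function(object) {
  cat("CoexNetwork:", igraph::vcount(object@graph), "genes,",
      igraph::ecount(object@graph), "edges; percentile",
      object@percentile, "(MI >=",
      format(object@thresholdValue, digits = 4), "nats)\n")
})

setMethod("show", "GenePartition", function(object) {
  cat("GenePartition:", length(object@membership), "genes in",
      object@nModules, "modules (", object@method, ")\n")
  cat("  L =", format(object@codelength, digits = 6), "bits;  Q =",
      format(object@modularityQ, digits = 6), "\n")
})

setMethod("show", "ModuleSimilarity", function(object) {
  cat("ModuleSimilarity:", nrow(object@jaccard), "x", ncol(object@jaccard),
      "modules; mean best-match Jaccard =",
      format(mean(object@matching$jaccard), digits = 4), "\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@terms), "terms over",
      length(object@universe), "universe genes\n")
})
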