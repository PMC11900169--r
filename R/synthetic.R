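#' Construct a synthetic two-condition study design
#'
#' The generator draws, per gene, a negative-binomial mean from a log-uniform
#' range, then produces counts through a Gaussian copula: genes in the same
#' module share a latent factor so that any pair has latent correlation
#' `within_module_rho`, and the latent normal is pushed through the NB
#' quantile function. Dependence is therefore genuinely non-linear on the
#' count scale, which is the regime mutual-information network inference is
#' designed for. Condition B reassigns a fixed fraction of each module's
#' genes round-robin to the other modules (planted rearrangement) and lets a
#' handful of background genes load on half of the module factors (planted
#' hubs).
#'
#' Defaults encode the package's reference validation study: 2000 genes, ten
#' modules of 50 genes, rho = 0.8, 150 samples per condition, 20\%
#' rearrangement, 5 planted hubs.
#'
#' @param n_genes gene-universe size.
#' @param n_samples_a,n_samples_b samples per condition (>= 4).
#' @param modules_a list of disjoint integer gene-index vectors; `NULL` plants
#'   ten modules of 50 genes at the start of the universe (truncated to fit).
#' @param rearrangement_fraction fraction of each module reassigned in B.
#' @param within_module_rho latent within-module correlation in `[0, 1)`.
#' @param n_hubs_b number of planted condition-B hub genes (taken from the
#'   background genes).
#' @param nb_mean_log_range log-scale range of per-gene NB means.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param library_size_range range of per-sample library sizes.
#' @param seed integer seed.
#' @return a validated [SyntheticDesign-class] object.
#' @examples
#' design <- syntheticDesign(n_genes = 200, n_samples_a = 20,
#'                           n_samples_b = 20,
#'                           modules_a = list(1:30, 31:60), seed = 7)
#' design
#' @export
syntheticDesign <- function(n_genes = 2000L,
                            n_samples_a = 150L,
                            n_samples_b = 150L,
                            modules_a = NULL,
                            rearrangement_fraction = 0.2,
                            within_module_rho = 0.8,
                            n_hubs_b = 5L,
                            nb_mean_log_range = c(log(5), log(500)),
                            nb_dispersion = 0.2,
                            library_size_range = c(5e6, 1.5e7),
                            seed = 42L) {
  if (is.null(modules_a)) {
    n_mod <- 10L
    size <- 50L
    modules_a <- list()
    start <- 1L
    for (m in seq_len(n_mod)) {
      end <- min(start + size - 1L, n_genes)
      if (end < start) break
      modules_a[[m]] <- start:end
      start <- end + 1L
    }
  }
  obj <- new("SyntheticDesign",
             nGenes = as.integer(n_genes),
             nSamplesA = as.integer(n_samples_a),
             nSamplesB = as.integer(n_samples_b),
             modulesA = lapply(modules_a, as.integer),
             rearrangementFraction = as.numeric(rearrangement_fraction),
             withinModuleRho = as.numeric(within_module_rho),
             nHubsB = as.integer(n_hubs_b),
             nbMeanLogRange = as.numeric(nb_mean_log_range),
             nbDispersion = as.numeric(nb_dispersion),
             librarySizeRange = as.numeric(library_size_range),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

# Round-robin reassignment of the first floor(f * |module|) genes of each
# module to the other modules; deterministic given module order. Returns the
# condition-B membership vector.
rearrangePartition <- function(partition_a, modules, fraction) {
  part_b <- partition_a
  n_mod <- length(modules)
  if (n_mod < 2L || fraction <= 0) return(part_b)
  for (m in seq_len(n_mod)) {
    genes <- modules[[m]]
    n_move <- floor(fraction * length(genes))
    if (n_move < 1L) next
    moved <- genes[seq_len(n_move)]
    offsets <- 1L + (seq_len(n_move) - 1L) %% (n_mod - 1L)
    targets <- ((m - 1L + offsets) %% n_mod) + 1L
    part_b[moved] <- targets
  }
  part_b
}

#' Generate two-condition RNA-seq counts with planted network structure
#'
#' See [syntheticDesign()] for the model. Both count matrices cover the same
#' gene universe; all randomness is governed by `design@seed`, so repeated
#' calls are byte-identical. The latent Gaussian matrices are kept in the
#' `metadata()` of each returned [SummarizedExperiment::SummarizedExperiment]
#' under `"latent"` so tests can check the copula's correlation structure
#' directly.
#'
#' @param design a [SyntheticDesign-class].
#' @return a list with elements `counts_a`, `counts_b` (SummarizedExperiment,
#'   assay `"counts"`, `colData$condition`) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' sim <- generateTwoConditionCounts(
#'   syntheticDesign(n_genes = 120, n_samples_a = 30, n_samples_b = 30,
#'                   modules_a = list(1:25, 26:50, 51:75), seed = 1))
#' sim$truth
#' @export
generateTwoConditionCounts <- function(design) {
  validObject(design)
  G <- design@nGenes
  modules <- design@modulesA
  n_mod <- length(modules)
  gene_ids <- sprintf("g%05d", seq_len(G))

  partition_a <- integer(G)
  for (m in seq_len(n_mod)) partition_a[modules[[m]]] <- m
  partition_b <- rearrangePartition(partition_a, modules, design@rearrangementFraction)

  background <- which(partition_a == 0L)
  if (design@nHubsB > length(background))
    stop("n_hubs_b: not enough background genes to plant ", design@nHubsB,
         " hubs", call. = FALSE)
  hubs <- background[seq_len(design@nHubsB)]

  withSeed(design@seed, {
    mu <- exp(stats::runif(G, design@nbMeanLogRange[1], design@nbMeanLogRange[2]))
    libs_a <- stats::runif(design@nSamplesA, design@librarySizeRange[1],
                           design@librarySizeRange[2])
    libs_b <- stats::runif(design@nSamplesB, design@librarySizeRange[1],
                           design@librarySizeRange[2])
    lat_a <- simulateLatent(G, design@nSamplesA, partition_a, n_mod,
                            design@withinModuleRho, hubs = integer())
    lat_b <- simulateLatent(G, design@nSamplesB, partition_b, n_mod,
                            design@withinModuleRho, hubs = hubs)
  })

  counts_a <- copulaCounts(lat_a, mu, libs_a, design@nbDispersion)
  counts_b <- copulaCounts(lat_b, mu, libs_b, design@nbDispersion)
  dimnames(counts_a) <- list(gene_ids, sprintf("A%03d", seq_len(ncol(counts_a))))
  dimnames(counts_b) <- list(gene_ids, sprintf("B%03d", seq_len(ncol(counts_b))))
  dimnames(lat_a) <- dimnames(counts_a)
  dimnames(lat_b) <- dimnames(counts_b)

  se_a <- makeCountSE(counts_a, condition = rep("A", ncol(counts_a)))
  se_b <- makeCountSE(counts_b, condition = rep("B", ncol(counts_b)))
  S4Vectors::metadata(se_a)$latent <- lat_a
  S4Vectors::metadata(se_b)$latent <- lat_b

  truth <- new("GroundTruth",
               partitionA = stats::setNames(partition_a, gene_ids),
               partitionB = stats::setNames(partition_b, gene_ids),
               hubGenesB = gene_ids[hubs],
               design = design)
  list(counts_a = se_a, counts_b = se_b, truth = truth)
}

# Latent Gaussian matrix: shared module factor + idiosyncratic noise.
# Hub genes load equally on ceiling(n_mod / 2) factors instead of one.
simulateLatent <- function(G, n, partition, n_mod, rho, hubs) {
  factors <- if (n_mod > 0L) matrix(stats::rnorm(n_mod * n), n_mod, n)
             else matrix(0, 0L, n)
  eps <- matrix(stats::rnorm(G * n), G, n)
  z <- eps
  in_mod <- partition > 0L
  if (any(in_mod) && rho > 0) {
    z[in_mod, ] <- sqrt(rho) * factors[partition[in_mod], , drop = FALSE] +
      sqrt(1 - rho) * eps[in_mod, , drop = FALSE]
  }
  if (length(hubs) && n_mod > 0L && rho > 0) {
    h <- ceiling(n_mod / 2)
    shared <- colSums(factors[seq_len(h), , drop = FALSE]) / sqrt(h)
    z[hubs, ] <- sqrt(rho) * matrix(shared, length(hubs), n, byrow = TRUE) +
      sqrt(1 - rho) * eps[hubs, , drop = FALSE]
  }
  z
}

# Map latent normals through the NB quantile function; per-sample depth is
# the library size relative to the mean library.
copulaCounts <- function(latent, mu, libs, dispersion) {
  s <- libs / mean(libs)
  mu_mat <- outer(mu, s)
  u <- stats::pnorm(latent)
  cts <- stats::qnbinom(u, size = 1 / dispersion, mu = mu_mat)
  matrix(as.integer(cts), nrow = nrow(latent), ncol = ncol(latent))
}

#' Generate GMT-style annotations matched to the planted modules
#'
#' Emits one "true" term per planted condition-A module, containing a random
#' `coverage` fraction of the module's genes, plus `n_decoy_terms` decoy terms
#' of random universe genes with sizes drawn from the true-term sizes. Every
#' term has at least 2 genes.
#'
#' @param truth a [GroundTruth-class].
#' @param n_decoy_terms number of decoy terms.
#' @param coverage fraction of each module annotated by its true term, in
#'   `(0, 1]`.
#' @param seed integer seed.
#' @return an [AnnotationSet-class]; true terms are named `TERM_M<k>`.
#' @export
generateAnnotations <- function(truth, n_decoy_terms = 10L, coverage = 0.8,
                                seed = 1L) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]", call. = FALSE)
  universe <- names(truth@partitionA)
  mod_ids <- sort(unique(truth@partitionA[truth@partitionA > 0L]))
  if (!length(mod_ids))
    stop("ground truth contains no planted modules", call. = FALSE)
  terms <- list()
  desc <- character()
  withSeed(seed, {
    sizes <- integer()
    for (m in mod_ids) {
      genes <- names(truth@partitionA)[truth@partitionA == m]
      if (length(genes) < 2L)
        stop("planted module ", m, " has fewer than 2 genes", call. = FALSE)
      k <- max(2L, round(coverage * length(genes)))
      picked <- if (k >= length(genes)) genes else sort(sample(genes, k))
      id <- sprintf("TERM_M%02d", m)
      terms[[id]] <- picked
      desc[id] <- sprintf("true term for planted module %d", m)
      sizes <- c(sizes, length(picked))
    }
    for (d in seq_len(n_decoy_terms)) {
      k <- sample(sizes, 1L)
      id <- sprintf("DECOY%03d", d)
      terms[[id]] <- sort(sample(universe, k))
      desc[id] <- "decoy term (random genes)"
    }
  })
  new("AnnotationSet", terms = terms, descriptions = desc,
      universe = universe)
}
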