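#' Discretize expression per gene
#'
#' Equal-frequency binning assigns balanced rank blocks (bin occupancies
#' differ by at most one; ties resolved by stable sample order), equal-width
#' binning splits `[min, max]` into `n_bins` even intervals. A constant gene
#' lands entirely in bin 0 — documented behaviour, not an error. The default
#' bin count is the cube-root rule `ceiling(n_samples^(1/3))`.
#'
#' @param x SummarizedExperiment with assay `"normexpr"` (or `"counts"`), or
#'   a numeric matrix, genes x samples.
#' @param method `"equal_frequency"` (default) or `"equal_width"`.
#' @param n_bins number of bins (>= 2); default cube-root rule.
#' @return a [DiscretizedMatrix-class].
#' @export
discretizeExpression <- function(x, method = c("equal_frequency", "equal_width"),
                                 n_bins = NULL) {
  method <- match.arg(method)
  m <- if (methods::is(x, "SummarizedExperiment")) {
    a <- SummarizedExperiment::assays(x)
    if ("normexpr" %in% names(a)) a$normexpr else a$counts
  } else {
    as.matrix(x)
  }
  n <- ncol(m)
  if (is.null(n_bins)) n_bins <- ceiling(n^(1 / 3))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  if (n < n_bins) stop("need at least n_bins samples", call. = FALSE)
  bins <- matrix(0L, nrow(m), n, dimnames = dimnames(m))
  if (method == "equal_frequency") {
    base <- n %/% n_bins
    extra <- n %% n_bins
    sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
    codes <- rep(0:(n_bins - 1L), times = sizes)
    for (g in seq_len(nrow(m))) {
      row <- m[g, ]
      if (max(row) == min(row)) next  # constant gene: all bin 0
      bins[g, order(row)] <- codes
    }
  } else {
    for (g in seq_len(nrow(m))) {
      row <- m[g, ]
      rng <- range(row)
      if (rng[1] == rng[2]) next
      breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
      bins[g, ] <- pmin(findInterval(row, breaks, rightmost.closed = TRUE),
                        n_bins) - 1L
    }
  }
  new("DiscretizedMatrix", bins = bins, nBins = n_bins, method = method)
}

#' Plug-in mutual information of two discrete vectors (nats)
#'
#' \eqn{\hat I = \sum_{x,y} \hat p(x,y) \ln[\hat p(x,y) / (\hat p(x)\hat
#' p(y))]} over the empirical joint distribution. Returns 0 whenever either
#' input is constant.
#'
#' @param x_bins,y_bins equal-length integer code vectors.
#' @return mutual information in nats (non-negative).
#' @export
mutualInformation <- function(x_bins, y_bins) {
  if (length(x_bins) != length(y_bins))
    stop("x_bins and y_bins must have equal length", call. = FALSE)
  if (length(x_bins) < 2L) stop("need at least 2 observations", call. = FALSE)
  n <- length(x_bins)
  joint <- table(x_bins, y_bins) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  hx <- -sum(xlogx(px))
  hy <- -sum(xlogx(py))
  hxy <- -sum(xlogx(joint))
  max(hx + hy - hxy, 0)
}

# Core pairwise-MI engine: for gene blocks, accumulate the joint entropy of
# every pair via indicator-matrix crossproducts (one BLAS call per bin pair),
# then MI = H_i + H_j - H_ij. Returns the full symmetric matrix in nats.
miMatrixCore <- function(bins, n_bins, chunk_size = 1024L) {
  G <- nrow(bins)
  n <- ncol(bins)
  ind <- lapply(0:(n_bins - 1L), function(b) {
    m <- matrix(0, G, n)
    m[bins == b] <- 1
    m
  })
  marg <- vapply(ind, rowSums, numeric(G))          # G x n_bins counts
  hmarg <- -rowSums(xlogx(marg / n))                # marginal entropies
  mi <- matrix(0, G, G)
  starts <- seq(1L, G, by = chunk_size)
  for (s in starts) {
    rows <- s:min(s + chunk_size - 1L, G)
    hj <- matrix(0, length(rows), G)
    for (a in seq_len(n_bins)) {
      ia <- ind[[a]][rows, , drop = FALSE]
      for (b in seq_len(n_bins)) {
        p <- tcrossprod(ia, ind[[b]]) / n
        hj <- hj - xlogx(p)
      }
    }
    mi[rows, ] <- outer(hmarg[rows], hmarg, "+") - hj
  }
  mi[mi < 0] <- 0
  dimnames(mi) <- list(rownames(bins), rownames(bins))
  mi
}

#' Pairwise mutual-information matrix over all gene pairs
#'
#' Computes the plug-in MI for every unordered gene pair of a discretized
#' matrix. Internally blocked for memory; results are independent of the
#' blocking.
#'
#' @param disc a [DiscretizedMatrix-class].
#' @param genes_subset optional gene ids restricting the computation.
#' @param chunk_size internal row-block size (does not affect results).
#' @return an [MIResult-class] (symmetric matrix, `NA` diagonal).
#' @export
miMatrix <- function(disc, genes_subset = NULL, chunk_size = 1024L) {
  bins <- disc@bins
  if (!is.null(genes_subset)) {
    missing <- setdiff(genes_subset, rownames(bins))
    if (length(missing))
      stop("genes not in matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    bins <- bins[genes_subset, , drop = FALSE]
  }
  if (nrow(bins) < 2L) stop("need at least 2 genes", call. = FALSE)
  mi <- miMatrixCore(bins, disc@nBins, chunk_size = as.integer(chunk_size))
  diag(mi) <- NA_real_
  new("MIResult", mi = mi, nSamples = ncol(bins), nBins = disc@nBins,
      method = disc@method)
}

# Upper-triangle pair view of an MIResult: data.frame(gene_a, gene_b, mi)
# with gene_a < gene_b in stored order.
miPairs <- function(mi_result) {
  m <- mi_result@mi
  ut <- upper.tri(m)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(gene_a = rownames(m)[idx[, 1]],
             gene_b = colnames(m)[idx[, 2]],
             mi = m[ut], stringsAsFactors = FALSE)
}

#' Build a co-expression network by percentile thresholding
#'
#' Keeps the top `k = floor((1 - percentile/100) * N_pairs)` gene pairs by MI
#' (descending); ties at the boundary are broken by lexicographic gene-pair
#' order so the construction is deterministic and both condition networks get
#' identical edge counts for a shared gene universe. The smallest retained MI
#' is recorded as the threshold; nodes are the genes with at least one
#' retained edge.
#'
#' @param mi_result an [MIResult-class].
#' @param percentile percentile in `[0, 100)`; default 99.99 (0 keeps every
#'   pair).
#' @return a [CoexNetwork-class].
#' @export
thresholdByPercentile <- function(mi_result, percentile = 99.99) {
  assertScalar(percentile, "percentile", 0, 100)
  if (percentile >= 100)
    stop("percentile must be below 100", call. = FALSE)
  pairs <- miPairs(mi_result)
  n_pairs <- nrow(pairs)
  # small epsilon guards against floating-point error in (1 - p/100)
  k <- floor((100 - percentile) / 100 * n_pairs + 1e-9)
  if (k < 1L)
    stop("percentile ", percentile, " keeps no edges for ", n_pairs,
         " pairs; choose a lower percentile", call. = FALSE)
  ord <- order(-pairs$mi, pairs$gene_a, pairs$gene_b, method = "radix")
  kept <- pairs[ord[seq_len(k)], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$gene_a, to = kept$gene_b, weight = kept$mi),
    directed = FALSE)
  new("CoexNetwork", graph = g, thresholdValue = min(kept$mi),
      percentile = percentile)
}

#' Basic network metrics across a percentile sweep
#'
#' For each percentile: node count, edge count, number of components, size of
#' the largest component and global transitivity of the thresholded network.
#' Percentiles that keep no edges yield a zero row rather than an error.
#'
#' @param mi_result an [MIResult-class].
#' @param percentiles percentiles to evaluate.
#' @return data.frame with one row per percentile.
#' @export
percentileSweep <- function(mi_result,
                            percentiles = c(99.9999, 99.999, 99.99, 99.9,
                                            99, 98, 90, 80)) {
  rows <- lapply(percentiles, function(p) {
    net <- tryCatch(thresholdByPercentile(mi_result, p),
                    error = function(e) NULL)
    if (is.null(net))
      return(data.frame(percentile = p, n_nodes = 0L, n_edges = 0L,
                        n_components = 0L, largest_component = 0L,
                        transitivity = 0))
    g <- asIgraph(net)
    comp <- igraph::components(g)
    data.frame(percentile = p,
               n_nodes = igraph::vcount(g),
               n_edges = igraph::ecount(g),
               n_components = comp$no,
               largest_component = max(comp$csize),
               transitivity = graphTransitivity(net))
  })
  do.call(rbind, rows)
}

#' Permutation null model for the MI threshold
#'
#' Each permutation independently shuffles every gene's sample order
#' (destroying all between-gene dependence while preserving marginals),
#' recomputes the pairwise MI distribution — on a random subsample of at most
#' `max_pairs` pairs when the pair count exceeds it — and records the
#' percentile value of that null distribution. The empirical p-value is the
#' fraction of permutations whose null threshold reaches the observed one.
#'
#' @param x SummarizedExperiment / matrix (see [discretizeExpression()]) or a
#'   [DiscretizedMatrix-class].
#' @param n_perm number of permutations (>= 10).
#' @param percentile percentile defining the threshold statistic.
#' @param seed integer seed.
#' @param max_pairs cap on the number of pairs scored per permutation.
#' @param n_bins,method discretization settings when `x` is not yet
#'   discretized.
#' @return list with `n_permutations`, `observed_threshold`,
#'   `null_thresholds`, `null_quantiles` (5/25/50/75/95\%), `p_value`,
#'   `seed`.
#' @export
permutationNull <- function(x, n_perm = 100L, percentile = 99.99, seed = 1L,
                            max_pairs = 1e5,
                            method = "equal_frequency", n_bins = NULL) {
  if (n_perm < 10L) stop("n_perm must be >= 10", call. = FALSE)
  disc <- if (methods::is(x, "DiscretizedMatrix")) x
          else discretizeExpression(x, method = method, n_bins = n_bins)
  bins <- disc@bins
  G <- nrow(bins)
  n <- ncol(bins)
  n_pairs <- G * (G - 1) / 2
  prob <- 1 - percentile / 100

  withSeed(seed, {
    use_subsample <- n_pairs > max_pairs
    if (use_subsample) {
      sel <- sample.int(n_pairs, max_pairs)
      idx <- pairIndexFromLinear(sel, G)
    }
    statOf <- function(b) {
      if (!use_subsample) {
        m <- miMatrixCore(b, disc@nBins)
        vals <- m[upper.tri(m)]
      } else {
        vals <- miPairSubset(b, disc@nBins, idx)
      }
      # k-th largest value, k as in thresholdByPercentile
      k <- max(1L, floor(prob * length(vals)))
      sort(vals, decreasing = TRUE)[k]
    }
    observed <- statOf(bins)
    null_thresholds <- vapply(seq_len(n_perm), function(i) {
      perm <- bins
      for (g in seq_len(G)) perm[g, ] <- bins[g, sample.int(n)]
      statOf(perm)
    }, numeric(1))
  })

  list(n_permutations = as.integer(n_perm),
       observed_threshold = observed,
       null_thresholds = null_thresholds,
       null_quantiles = stats::quantile(null_thresholds,
                                        c(0.05, 0.25, 0.5, 0.75, 0.95)),
       p_value = mean(null_thresholds >= observed),
       seed = as.integer(seed))
}

# Map linear upper-triangle indices (column-major, i < j) to (i, j) pairs.
pairIndexFromLinear <- function(sel, G) {
  # pair t within column j occupies linear positions (j-1)(j-2)/2 + 1 .. +j-1
  bounds <- c(0, cumsum(seq_len(G - 1)))  # linear index ranges per column
  j <- findInterval(sel - 1, bounds) + 1L # column index (2..G)
  i <- sel - bounds[j - 1L]
  cbind(i = i, j = j)
}

# MI for an explicit list of gene pairs via joint-code tabulation.
miPairSubset <- function(bins, n_bins, idx) {
  n <- ncol(bins)
  marg <- vapply(0:(n_bins - 1L), function(b) rowSums(bins == b),
                 numeric(nrow(bins)))
  hmarg <- -rowSums(xlogx(marg / n))
  vapply(seq_len(nrow(idx)), function(r) {
    x <- bins[idx[r, 1], ]
    y <- bins[idx[r, 2], ]
    joint <- tabulate(x * n_bins + y + 1L, nbins = n_bins * n_bins) / n
    hxy <- -sum(xlogx(joint))
    max(hmarg[idx[r, 1]] + hmarg[idx[r, 2]] - hxy, 0)
  }, numeric(1))
}
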