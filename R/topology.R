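#' Degree distribution summary
#'
#' Per-node degrees, the empirical degree histogram p(k) and the cumulative
#' tail P(K >= k) over observed degrees.
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @return list with `degree` (named), `histogram` (data.frame `k`, `count`,
#'   `p`), `cumulative` (data.frame `k`, `p_ge`).
#' @export
degreeSummary <- function(net) {
  g <- resolveGraph(net)
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  deg <- igraph::degree(g)
  tab <- table(deg)
  k <- as.integer(names(tab))
  p <- as.numeric(tab) / length(deg)
  cum <- rev(cumsum(rev(p)))
  list(degree = deg,
       histogram = data.frame(k = k, count = as.integer(tab), p = p),
       cumulative = data.frame(k = k, p_ge = cum))
}

#' Log-log scaling exponent of the degree distribution
#'
#' Ordinary least squares of `ln p(k)` on `ln k` over the degrees with
#' non-zero frequency; returns the negated slope. This is the straight-line
#' reading of the log-log degree histogram, not a maximum-likelihood
#' power-law fit (see [fitDegreeDistributions()] for those).
#'
#' @param summary output of [degreeSummary()].
#' @return scaling exponent gamma.
#' @export
fitGammaLogLog <- function(summary) {
  h <- summary$histogram
  h <- h[h$p > 0 & h$k > 0, , drop = FALSE]
  if (nrow(h) < 3L)
    stop("need at least 3 distinct degrees with non-zero frequency",
         call. = FALSE)
  fit <- stats::lm(log(p) ~ log(k), data = h)
  -unname(stats::coef(fit)[2])
}

#' Maximum-likelihood fits of candidate degree distributions
#'
#' Fits discrete power-law (Zipf with k_min = 1), Poisson, shifted geometric,
#' negative binomial and a normal on log-degree, ranks them by AIC
#' (= 2 * n_params - 2 * loglik) and flags the best. Degenerate fits yield NA
#' rows rather than errors.
#'
#' @param summary output of [degreeSummary()] (or a [CoexNetwork-class]).
#' @return data.frame with columns `distribution`, `n_params`, `loglik`,
#'   `aic`, `best`.
#' @export
fitDegreeDistributions <- function(summary) {
  if (methods::is(summary, "CoexNetwork") || igraph::is_igraph(summary))
    summary <- degreeSummary(summary)
  k <- as.integer(summary$degree)
  if (length(k) < 10L) stop("need at least 10 nodes", call. = FALSE)
  n <- length(k)
  rows <- list()

  # Zipf / discrete power-law on k >= 1: p(k) = k^-s / zeta(s)
  kp <- k[k >= 1L]
  rows$power_law <- tryCatch({
    ll_zipf <- function(s) -s * sum(log(kp)) - length(kp) * log(pracma::zeta(s))
    opt <- stats::optimize(ll_zipf, c(1.0001, 25), maximum = TRUE)
    c(n_params = 1, loglik = opt$objective)
  }, error = function(e) c(n_params = 1, loglik = NA_real_))

  rows$poisson <- tryCatch({
    lam <- mean(k)
    c(n_params = 1, loglik = sum(stats::dpois(k, lam, log = TRUE)))
  }, error = function(e) c(n_params = 1, loglik = NA_real_))

  # geometric shifted to the minimum observed degree (discretized exponential)
  rows$geometric <- tryCatch({
    sh <- k - min(k)
    p <- 1 / (mean(sh) + 1)
    c(n_params = 1, loglik = sum(stats::dgeom(sh, p, log = TRUE)))
  }, error = function(e) c(n_params = 1, loglik = NA_real_))

  rows$negative_binomial <- tryCatch({
    fit <- suppressWarnings(MASS::fitdistr(k, "negative binomial"))
    c(n_params = 2, loglik = as.numeric(fit$loglik))
  }, error = function(e) c(n_params = 2, loglik = NA_real_))

  rows$lognormal <- tryCatch({
    lk <- log(k[k >= 1L])
    mu <- mean(lk)
    sd_mle <- sqrt(mean((lk - mu)^2))
    # Jacobian term puts the log-degree normal on the same (count) scale
    # as the discrete candidates, keeping AICs comparable
    c(n_params = 2,
      loglik = sum(stats::dnorm(lk, mu, sd_mle, log = TRUE)) - sum(lk))
  }, error = function(e) c(n_params = 2, loglik = NA_real_))

  tab <- data.frame(distribution = names(rows),
                    n_params = vapply(rows, `[[`, numeric(1), "n_params"),
                    loglik = vapply(rows, `[[`, numeric(1), "loglik"),
                    row.names = NULL)
  tab$aic <- 2 * tab$n_params - 2 * tab$loglik
  tab$best <- !is.na(tab$aic) & tab$aic == min(tab$aic, na.rm = TRUE)
  tab[order(tab$aic), , drop = FALSE]
}

#' Two-sample Kolmogorov-Smirnov test on degree samples
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' the asymptotic two-sided one by default (degrees are discrete, so ties are
#' expected and the exact variant is only available on request).
#'
#' @param deg_a,deg_b numeric degree samples.
#' @param exact use the exact small-sample distribution?
#' @return list with `D` and `p_value`.
#' @export
ksDegreeTest <- function(deg_a, deg_b, exact = FALSE) {
  if (!length(deg_a) || !length(deg_b))
    stop("both degree samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(deg_a, deg_b, exact = exact))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Global transitivity (3 x triangles / connected triples)
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @return transitivity in `[0, 1]`; 0 when the graph has no connected
#'   triples.
#' @export
graphTransitivity <- function(net) {
  g <- resolveGraph(net)
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr) || is.na(tr)) 0 else tr
}

#' Diameter and component census
#'
#' Diameter is the largest finite shortest-path length, i.e. the maximum over
#' components when the graph is disconnected.
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @return list with `diameter`, `n_components`, `largest_component`,
#'   `component_sizes`.
#' @export
diameterComponents <- function(net) {
  g <- resolveGraph(net)
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  comp <- igraph::components(g)
  list(diameter = igraph::diameter(g, unconnected = TRUE, weights = NA),
       n_components = comp$no,
       largest_component = max(comp$csize),
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Jaccard similarity of two networks' edge sets
#'
#' |E_a intersect E_b| / |E_a union E_b| over unordered gene pairs.
#'
#' @param net_a,net_b [CoexNetwork-class] or igraph objects over a shared
#'   gene-id space.
#' @return proportion in `[0, 1]`.
#' @export
edgeJaccard <- function(net_a, net_b) {
  ea <- edgeKeys(resolveGraph(net_a))
  eb <- edgeKeys(resolveGraph(net_b))
  un <- union(ea, eb)
  if (!length(un)) stop("both networks are empty", call. = FALSE)
  length(intersect(ea, eb)) / length(un)
}

#' Unnormalized shortest-path betweenness centrality
#'
#' Each unordered node pair is counted once; shortest-path multiplicity is
#' shared fractionally. Values are raw path counts (no normalization), so
#' they match the magnitudes usually reported for co-expression networks.
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @return named numeric vector.
#' @export
nodeBetweenness <- function(net) {
  g <- resolveGraph(net)
  igraph::betweenness(g, directed = FALSE, normalized = FALSE, weights = NA)
}

#' Top fraction of genes by score
#'
#' Returns the `ceiling(fraction * n)` highest-scoring genes; genes tied with
#' the k-th score are all included, so the set can exceed the nominal size at
#' boundary ties (and equals all genes when every score ties).
#'
#' @param scores named numeric vector (gene -> score).
#' @param fraction fraction in (0, 1); default 0.10.
#' @return character vector of gene ids.
#' @export
topFraction <- function(scores, fraction = 0.10) {
  assertScalar(fraction, "fraction", 0, 1)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly in (0, 1)", call. = FALSE)
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  k <- ceiling(fraction * length(scores))
  cutoff <- sort(scores, decreasing = TRUE)[k]
  names(scores)[scores >= cutoff]
}

#' Centrality table with hub / high-betweenness flags
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @param fraction top fraction defining hubs and brokers (default 0.10).
#' @return data.frame `gene`, `degree`, `betweenness`, `is_hub`,
#'   `is_high_betweenness`.
#' @export
centralityTable <- function(net, fraction = 0.10) {
  g <- resolveGraph(net)
  deg <- igraph::degree(g)
  btw <- nodeBetweenness(g)
  hubs <- topFraction(deg, fraction)
  brokers <- topFraction(btw, fraction)
  data.frame(gene = names(deg), degree = as.integer(deg),
             betweenness = unname(btw),
             is_hub = names(deg) %in% hubs,
             is_high_betweenness = names(deg) %in% brokers,
             row.names = NULL)
}

#' Shared / exclusive partition of two gene sets
#'
#' Percentages are relative to the union (Venn-diagram semantics).
#'
#' @param set_a,set_b character vectors.
#' @return list with `shared`, `a_only`, `b_only`, counts and percentages.
#' @export
compareGeneSets <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  a_only <- setdiff(set_a, set_b)
  b_only <- setdiff(set_b, set_a)
  n_union <- length(union(set_a, set_b))
  pct <- function(x) if (n_union) 100 * length(x) / n_union else NA_real_
  list(shared = shared, a_only = a_only, b_only = b_only,
       n_shared = length(shared), n_a_only = length(a_only),
       n_b_only = length(b_only), n_union = n_union,
       pct_shared = pct(shared), pct_a_only = pct(a_only),
       pct_b_only = pct(b_only))
}

#' Neighbors gained by genes between two networks
#'
#' For each query gene g, the set `neighbors_b(g) \\ neighbors_a(g)` (the
#' neighbor set in A is empty when g is absent from network A). The common
#' gained set contains the genes gained by every query gene.
#'
#' @param net_a,net_b [CoexNetwork-class] or igraph objects.
#' @param genes query gene ids (must be present in `net_b`; an error is
#'   raised for genes absent from both networks).
#' @return list with `gained` (named list), `mean_gain`, `common_gained`.
#' @export
neighborGain <- function(net_a, net_b, genes) {
  ga <- resolveGraph(net_a)
  gb <- resolveGraph(net_b)
  va <- igraph::V(ga)$name
  vb <- igraph::V(gb)$name
  absent <- setdiff(genes, union(va, vb))
  if (length(absent))
    stop("gene(s) absent from both networks: ",
         paste(absent, collapse = ", "), call. = FALSE)
  gained <- lapply(genes, function(g) {
    nb <- if (g %in% vb)
      igraph::V(gb)$name[igraph::neighbors(gb, g)] else character()
    na_ <- if (g %in% va)
      igraph::V(ga)$name[igraph::neighbors(ga, g)] else character()
    setdiff(nb, na_)
  })
  names(gained) <- genes
  common <- if (length(gained)) Reduce(intersect, gained) else character()
  list(gained = gained,
       mean_gain = mean(lengths(gained)),
       common_gained = common)
}

#' Induced subgraph over a gene set
#'
#' Genes not present in the network are dropped with a warning carrying the
#' dropped count; an edgeless result is allowed.
#'
#' @param net a [CoexNetwork-class].
#' @param genes gene ids to retain.
#' @return a [CoexNetwork-class].
#' @export
inducedCoexSubgraph <- function(net, genes) {
  g <- resolveGraph(net)
  present <- intersect(genes, igraph::V(g)$name)
  dropped <- length(genes) - length(present)
  if (dropped > 0L)
    warning(dropped, " gene(s) not in the network were dropped",
            call. = FALSE)
  sub <- igraph::induced_subgraph(g, present)
  new("CoexNetwork", graph = sub,
      thresholdValue = if (methods::is(net, "CoexNetwork"))
        net@thresholdValue else NA_real_,
      percentile = if (methods::is(net, "CoexNetwork"))
        net@percentile else NA_real_)
}

#' Degree-preserving rewiring null model
#'
#' Replicates of double-edge swaps that preserve the degree sequence exactly;
#' reports null distributions of transitivity and diameter and the empirical
#' p-value of the observed transitivity (fraction of null replicates at or
#' above it).
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @param n_rewires swaps per replicate (at least 10 x edge count).
#' @param n_replicates number of null replicates.
#' @param seed integer seed.
#' @return list with `transitivity` (null vector), `diameter` (null vector),
#'   summary means/sds, `p_transitivity`, `observed_transitivity`.
#' @export
rewiringNull <- function(net, n_rewires = NULL, n_replicates = 100L,
                         seed = 1L) {
  g <- resolveGraph(net)
  m <- igraph::ecount(g)
  if (is.null(n_rewires)) n_rewires <- 10L * m
  if (n_rewires < 10L * m)
    stop("n_rewires must be at least 10 * |E| = ", 10L * m, call. = FALSE)
  obs <- graphTransitivity(g)
  withSeed(seed, {
    trans <- numeric(n_replicates)
    diam <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = n_rewires))
      trans[r] <- graphTransitivity(gr)
      diam[r] <- igraph::diameter(gr, unconnected = TRUE, weights = NA)
    }
  })
  list(transitivity = trans, diameter = diam,
       null_mean_transitivity = mean(trans),
       null_sd_transitivity = stats::sd(trans),
       null_mean_diameter = mean(diam),
       null_sd_diameter = stats::sd(diam),
       observed_transitivity = obs,
       p_transitivity = mean(trans >= obs),
       seed = as.integer(seed))
}

#' Degree assortativity of a network
#'
#' @param net a [CoexNetwork-class] or igraph object.
#' @return the degree-assortativity coefficient.
#' @export
degreeAssortativity <- function(net) {
  g <- resolveGraph(net)
  igraph::assortativity_degree(g, directed = FALSE)
}

# Accept either a CoexNetwork or a bare igraph in topology entry points.
resolveGraph <- function(net) {
  if (methods::is(net, "CoexNetwork")) return(net@graph)
  if (igraph::is_igraph(net)) return(net)
  stop("expected a CoexNetwork or igraph object", call. = FALSE)
}
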