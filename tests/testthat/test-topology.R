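named_graph <- function(el, n = max(el)) {
  g <- igraph::make_graph(t(el), n = n, directed = FALSE)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

test_that("degree summaries cover histogram and cumulative tail", {
  tri <- named_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
  ds <- degreeSummary(tri)
  expect_equal(ds$histogram$p, 1)
  expect_equal(ds$histogram$k, 2)
  star <- named_graph(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  ds2 <- degreeSummary(star)
  expect_equal(ds2$histogram$count[ds2$histogram$k == 1], 4L)
  expect_equal(ds2$histogram$count[ds2$histogram$k == 4], 1L)
  # cumulative tail at the minimum degree is 1
  expect_equal(ds2$cumulative$p_ge[1], 1)
  expect_true(all(diff(ds2$cumulative$p_ge) <= 0))
  expect_equal(sum(ds2$histogram$p), 1)
})

test_that("log-log degree exponent is exact on collinear input", {
  k <- 1:50
  p <- k^(-0.8)
  p <- p / sum(p)
  summary <- list(histogram = data.frame(k = k, p = p))
  # normalization shifts the intercept, not the slope
  expect_equal(fitGammaLogLog(summary), 0.8, tolerance = 1e-9)
  # a regular graph has a single support point
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  expect_error(fitGammaLogLog(degreeSummary(ring)), "3 distinct degrees")
})

test_that("noisy synthetic power-law degrees recover gamma approximately", {
  set.seed(31)
  k <- 1:40
  p <- k^(-1.2) / sum(k^(-1.2))
  counts <- as.vector(rmultinom(1, 5000, p))
  h <- data.frame(k = k, p = counts / sum(counts))
  h <- h[h$p > 0, ]
  expect_equal(fitGammaLogLog(list(histogram = h)), 1.2, tolerance = 0.15 / 1.2)
})

test_that("AIC model selection identifies the generating degree distribution", {
  set.seed(17)
  k <- rpois(2000, 8)
  pois <- list(degree = k[k > 0])  # network degrees are always positive
  tab <- fitDegreeDistributions(pois)
  expect_equal(tab$distribution[tab$best], "poisson")
  expect_equal(tab$aic, 2 * tab$n_params - 2 * tab$loglik)
  # Zipf degrees: inverse-CDF sampling from p(k) ~ k^-2.2
  kmax <- 5000
  pz <- (1:kmax)^(-2.2)
  z <- sample(1:kmax, 2000, replace = TRUE, prob = pz)
  tabz <- fitDegreeDistributions(list(degree = z))
  expect_equal(tabz$distribution[tabz$best], "power_law")
  expect_error(fitDegreeDistributions(list(degree = c(1, 2))), "10 nodes")
})

test_that("two-sample K-S statistic matches ECDF enumeration", {
  ks0 <- ksDegreeTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ks0$D, 0)
  expect_equal(ks0$p_value, 1)
  ks1 <- ksDegreeTest(c(1, 1, 2), c(2, 2, 3))
  expect_equal(ks1$D, 2 / 3)
  # rank invariance under a common monotone relabeling
  ks2 <- ksDegreeTest(c(10, 10, 40), c(40, 40, 90))
  expect_equal(ks2$D, ks1$D)
})

test_that("transitivity counts triangles over connected triples", {
  expect_equal(graphTransitivity(named_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))), 1)
  expect_equal(graphTransitivity(named_graph(rbind(c(1, 2), c(2, 3)))), 0)
  k4_minus <- named_graph(rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(graphTransitivity(k4_minus), 0.75)  # 6 / 8
})

test_that("diameter and components handle disconnected graphs", {
  path5 <- named_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  dc <- diameterComponents(path5)
  expect_equal(dc$diameter, 4)
  expect_equal(dc$n_components, 1L)
  two_tri <- named_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                               c(4, 5), c(5, 6), c(4, 6)))
  dc2 <- diameterComponents(two_tri)
  expect_equal(dc2$diameter, 1)
  expect_equal(dc2$n_components, 2L)
  expect_equal(dc2$largest_component, 3L)
})

test_that("edge Jaccard follows set arithmetic and is symmetric", {
  g1 <- named_graph(rbind(c(1, 2), c(2, 3), c(3, 4)), n = 5)
  g2 <- named_graph(rbind(c(2, 3), c(3, 4), c(4, 5)), n = 5)
  expect_equal(edgeJaccard(g1, g2), 0.5)  # {bc,cd} over 4
  expect_equal(edgeJaccard(g2, g1), 0.5)
  expect_equal(edgeJaccard(g1, g1), 1)
  g3 <- named_graph(rbind(c(1, 5)), n = 5)
  expect_equal(edgeJaccard(g1, g3), 0)
})

test_that("betweenness matches path enumeration on canonical graphs", {
  path3 <- named_graph(rbind(c(1, 2), c(2, 3)))
  b <- nodeBetweenness(path3)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))
  star <- named_graph(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(unname(nodeBetweenness(star)["a"]), 6)  # C(4,2)
  # complete graph: all zero
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_true(all(nodeBetweenness(k5) == 0))
})

test_that("top-fraction selection includes boundary ties", {
  s <- setNames(20:1, sprintf("g%02d", 1:20))
  expect_identical(topFraction(s, 0.10), c("g01", "g02"))
  tied <- setNames(c(5, 5, 4, 3, 2, 2, 1, 1, 1, 1), sprintf("g%02d", 1:10))
  expect_setequal(topFraction(tied, 0.10), c("g01", "g02"))
  allsame <- setNames(rep(3, 10), sprintf("g%02d", 1:10))
  expect_length(topFraction(allsame, 0.10), 10L)
  # always at least ceiling(f * n) genes
  set.seed(12)
  for (i in 1:20) {
    sc <- setNames(sample(1:6, 15, replace = TRUE), sprintf("x%02d", 1:15))
    expect_gte(length(topFraction(sc, 0.2)), ceiling(0.2 * 15))
  }
})

test_that("gene-set comparison reports union-relative percentages", {
  cmp <- compareGeneSets(sprintf("g%d", 1:10), sprintf("g%d", 5:14))
  expect_equal(cmp$n_shared, 6L)
  expect_equal(cmp$pct_shared, 100 * 6 / 14)
  same <- compareGeneSets(letters[1:4], letters[1:4])
  expect_equal(same$pct_shared, 100)
  disj <- compareGeneSets(letters[1:3], letters[4:6])
  expect_equal(disj$pct_shared, 0)
})

test_that("neighbor gains are set differences with a common core", {
  a <- named_graph(rbind(c(1, 2), c(1, 3)), n = 6)
  b <- named_graph(rbind(c(1, 2), c(1, 4), c(1, 5), c(2, 4), c(2, 5),
                         c(3, 6)), n = 6)
  ng <- neighborGain(a, b, c("a", "b"))
  expect_setequal(ng$gained$a, c("d", "e"))
  expect_setequal(ng$gained$b, c("d", "e"))
  expect_setequal(ng$common_gained, c("d", "e"))
  expect_equal(ng$mean_gain, 2)
  # identical networks gain nothing
  ng0 <- neighborGain(a, a, c("a", "b"))
  expect_true(all(lengths(ng0$gained) == 0))
  # a gene absent from net_a gains its whole net_b neighborhood
  ng1 <- neighborGain(a, b, "f")
  expect_setequal(ng1$gained$f, "c")
  expect_error(neighborGain(a, b, "z"), "absent from both")
})

test_that("induced subgraphs keep exactly the internal edges", {
  net <- toy_mi_network()
  g <- asIgraph(net)
  genes <- igraph::V(g)$name[1:10]
  sub <- inducedCoexSubgraph(net, genes)
  keys <- micoexdiff:::edgeKeys(asIgraph(sub))
  full <- micoexdiff:::edgeKeys(g)
  oracle <- full[vapply(strsplit(full, "|", fixed = TRUE),
                        function(p) all(p %in% genes), logical(1))]
  expect_setequal(keys, oracle)
  # identity when all nodes are retained
  all_sub <- inducedCoexSubgraph(net, igraph::V(g)$name)
  expect_equal(igraph::ecount(asIgraph(all_sub)), igraph::ecount(g))
  expect_warning(inducedCoexSubgraph(net, c(genes, "not_a_gene")), "dropped")
  # leaves of a star induce an edgeless graph
  star <- named_graph(rbind(c(1, 2), c(1, 3), c(1, 4)))
  leaf_sub <- inducedCoexSubgraph(
    new("CoexNetwork", graph = star, thresholdValue = 0, percentile = 0),
    c("b", "c", "d"))
  expect_equal(igraph::ecount(asIgraph(leaf_sub)), 0L)
})

test_that("degree-preserving rewiring nulls expose planted clustering", {
  net <- toy_mi_network()
  g <- asIgraph(net)
  res <- rewiringNull(net, n_rewires = 10L * igraph::ecount(g),
                      n_replicates = 30L, seed = 4L)
  # degree sequence preserved in every replicate is implied by the method;
  # check the observed clustering exceeds the null band
  expect_gt(res$observed_transitivity, quantile(res$transitivity, 0.95))
  expect_lte(res$p_transitivity, 0.05)
  res2 <- rewiringNull(net, n_rewires = 10L * igraph::ecount(g),
                       n_replicates = 30L, seed = 4L)
  expect_identical(res, res2)
  expect_error(rewiringNull(net, n_rewires = 3L), "at least 10")
  # explicit degree-sequence preservation on one seeded rewire
  gr <- withr::with_seed(1, igraph::rewire(
    g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g))))
  expect_identical(sort(igraph::degree(gr)), sort(igraph::degree(g)))
})

test_that("centrality tables flag top-decile hubs and brokers", {
  net <- toy_mi_network()
  ct <- centralityTable(net, 0.10)
  n <- nrow(ct)
  expect_gte(sum(ct$is_hub), ceiling(0.10 * n))
  expect_gte(sum(ct$is_high_betweenness), ceiling(0.10 * n))
  expect_equal(min(ct$degree[ct$is_hub]) >=
                 max(ct$degree[!ct$is_hub]), TRUE)
  expect_true(all(ct$betweenness >= 0))
})
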