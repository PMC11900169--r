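test_that("equal-frequency binning assigns balanced rank blocks", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  d <- discretizeExpression(m, n_bins = 3)
  expect_identical(unname(d@bins[1, ]), c(0L, 0L, 1L, 1L, 2L, 2L))
  # balanced occupancies for arbitrary n
  for (n in c(7, 10, 11)) {
    set.seed(n)
    row <- matrix(rnorm(n), 1, dimnames = list("g", paste0("s", 1:n)))
    occ <- table(discretizeExpression(row, n_bins = 3)@bins)
    expect_lte(max(occ) - min(occ), 1)
  }
  # constant gene: all samples in bin 0, not an error
  const <- matrix(5, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  expect_identical(unname(discretizeExpression(const, n_bins = 3)@bins[1, ]),
                   rep(0L, 6))
})

test_that("equal-width binning splits the range evenly", {
  m <- matrix(c(0, 0, 0, 10), 1, dimnames = list("g", paste0("s", 1:4)))
  d <- discretizeExpression(m, method = "equal_width", n_bins = 2)
  expect_identical(unname(d@bins[1, ]), c(0L, 0L, 0L, 1L))
})

test_that("plug-in MI reproduces its entropy identities", {
  expect_equal(mutualInformation(c(0, 1, 0, 1), c(0, 1, 0, 1)), log(2))
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 0, 0, 1)),
               0.693147 + 0.562335 - 1.039721, tolerance = 1e-5)
  expect_error(mutualInformation(c(0, 1), c(0, 1, 1)), "equal length")
  # constant input gives 0
  expect_equal(mutualInformation(rep(0, 5), c(0, 1, 0, 1, 1)), 0)
})

test_that("MI matrix equals pairwise plug-in calls and ignores chunking", {
  set.seed(2)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:12)))
  d <- discretizeExpression(m, n_bins = 3)
  res <- miMatrix(d)
  mi <- miValues(res)
  expect_true(all(is.na(diag(mi))))
  expect_equal(mi, t(mi))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(mi[i, j], mutualInformation(d@bins[i, ], d@bins[j, ]),
                 tolerance = 1e-12)
  }
  res2 <- miMatrix(d, chunk_size = 3L)
  expect_equal(miValues(res2), mi)
  # duplicated gene rows: MI equals the bin entropy
  d2 <- d
  d2@bins[2, ] <- d2@bins[1, ]
  tab <- table(d2@bins[1, ]) / ncol(d2@bins)
  expect_equal(miValues(miMatrix(d2))[1, 2], -sum(tab * log(tab)))
})

test_that("self-information bounds pairwise MI under shared binning", {
  set.seed(7)
  m <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:12)))
  d <- discretizeExpression(m, n_bins = 3)
  mi <- miValues(miMatrix(d))
  for (i in 1:8) {
    h <- mutualInformation(d@bins[i, ], d@bins[i, ])
    expect_true(all(mi[i, -i] <= h + 1e-12))
  }
})

test_that("percentile thresholding keeps the documented top-k with stable ties", {
  set.seed(3)
  m <- matrix(0, 142, 142)  # 10011 pairs
  m[upper.tri(m)] <- sample(seq_len(142 * 141 / 2))
  m <- m + t(m)
  diag(m) <- NA
  ids <- sprintf("g%03d", 1:142)
  dimnames(m) <- list(ids, ids)
  res <- new("MIResult", mi = m, nSamples = 10L, nBins = 3L,
             method = "equal_frequency")
  net <- thresholdByPercentile(res, 99.99)
  expect_equal(igraph::ecount(asIgraph(net)), 1L)  # floor(1e-4 * 10011) = 1
  expect_equal(thresholdValue(net), max(m, na.rm = TRUE))
  expect_error(thresholdByPercentile(res, 99.99999), "lower percentile")
  # near-zero percentile keeps every pair
  net_all <- thresholdByPercentile(res, 0)
  expect_equal(igraph::ecount(asIgraph(net_all)), 142 * 141 / 2)
  # tie at the boundary resolves by lexicographic gene pair
  m2 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m2[upper.tri(m2)] <- 1  # all tied
  m2 <- m2 + t(m2); diag(m2) <- NA
  res2 <- new("MIResult", mi = m2, nSamples = 10L, nBins = 2L,
              method = "equal_frequency")
  net2 <- thresholdByPercentile(res2, 80)  # keeps floor(0.2*10) = 2 pairs
  ek <- sort(micoexdiff:::edgeKeys(asIgraph(net2)))
  expect_identical(ek, c("a|b", "a|c"))
})

test_that("both condition networks get equal edge counts over a shared universe", {
  sim <- small_sim()
  mi_a <- miMatrix(discretizeExpression(sim$counts_a))
  mi_b <- miMatrix(discretizeExpression(sim$counts_b))
  for (pct in c(99.5, 99, 95)) {
    net_a <- thresholdByPercentile(mi_a, pct)
    net_b <- thresholdByPercentile(mi_b, pct)
    expect_equal(igraph::ecount(asIgraph(net_a)),
                 igraph::ecount(asIgraph(net_b)))
  }
})

test_that("the percentile sweep is monotone and composes with thresholding", {
  mi <- {
    toy_mi_network()  # populate cache
    .fixture_cache$mi
  }
  sweep <- percentileSweep(mi, c(99.9999, 99.99, 99.9, 99, 95))
  expect_true(all(diff(sweep$n_edges) >= 0))  # increasing as pct decreases
  # degenerate row reported as zeros (99.9999 of 7140 pairs keeps none)
  expect_equal(sweep$n_edges[1], 0L)
  expect_equal(sweep$n_nodes[1], 0L)
  row <- sweep[sweep$percentile == 99, ]
  net <- thresholdByPercentile(mi, 99)
  expect_equal(row$n_nodes, igraph::vcount(asIgraph(net)))
  expect_equal(row$n_edges, igraph::ecount(asIgraph(net)))
  expect_equal(row$transitivity, graphTransitivity(net))
  comp <- igraph::components(asIgraph(net))
  expect_equal(row$n_components, comp$no)
  expect_equal(row$largest_component, max(comp$csize))
})

test_that("network construction is deterministic", {
  sim <- small_sim()
  n1 <- thresholdByPercentile(miMatrix(discretizeExpression(sim$counts_a)), 99)
  n2 <- thresholdByPercentile(miMatrix(discretizeExpression(sim$counts_a)), 99)
  expect_identical(sort(micoexdiff:::edgeKeys(asIgraph(n1))), sort(micoexdiff:::edgeKeys(asIgraph(n2))))
  expect_equal(thresholdValue(n1), thresholdValue(n2))
})

test_that("the permutation null separates planted dependence from noise", {
  # independent genes: the observed threshold sits inside the null band
  design0 <- syntheticDesign(n_genes = 80L, n_samples_a = 40L,
                             n_samples_b = 40L,
                             modules_a = list(1:20, 21:40),
                             within_module_rho = 0, n_hubs_b = 0L,
                             seed = 15L)
  sim0 <- generateTwoConditionCounts(design0)
  # normalize first: raw counts share per-sample depth, which is itself a
  # (real) source of between-gene dependence the pipeline removes
  norm0 <- normalizeCounts(sim0$counts_a, tmmFactors(sim0$counts_a))
  rep0 <- permutationNull(norm0, n_perm = 60L, percentile = 99,
                          seed = 2L)
  expect_gte(rep0$p_value, 0.05)
  expect_gte(rep0$observed_threshold, rep0$null_quantiles[["5%"]])
  expect_lte(rep0$observed_threshold, rep0$null_quantiles[["95%"]])

  # planted rho = 0.8: the observed threshold beats every permutation
  sim1 <- small_sim()
  rep1 <- permutationNull(sim1$counts_a, n_perm = 60L, percentile = 99,
                          seed = 2L)
  expect_equal(rep1$p_value, 0)
  expect_gt(rep1$observed_threshold, max(rep1$null_thresholds))

  # identical seeds give identical reports
  rep2 <- permutationNull(sim1$counts_a, n_perm = 60L, percentile = 99,
                          seed = 2L)
  expect_identical(rep1, rep2)
  expect_error(permutationNull(sim1$counts_a, n_perm = 5L), "n_perm")
})

test_that("pair subsampling matches the full MI computation pairwise", {
  set.seed(9)
  m <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
  d <- discretizeExpression(m, n_bins = 3)
  full <- miValues(miMatrix(d))
  idx <- micoexdiff:::pairIndexFromLinear(seq_len(30 * 29 / 2), 30L)
  sub <- micoexdiff:::miPairSubset(d@bins, 3L, idx)
  expect_equal(sub, full[cbind(idx[, 1], idx[, 2])], tolerance = 1e-12)
})
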