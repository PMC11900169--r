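# Literal reimplementation of the Robinson-Oshlack weighted trimmed mean of
# M-values, written straight from the published formula, as the oracle for
# tmmFactors().
oracle_tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  # reference: sample whose upper-quartile CPM is closest to the mean
  uq <- apply(t(t(counts) / lib), 2, quantile, probs = 0.75)
  ref_i <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    oracle_tmm_pair(counts[, j], counts[, ref_i], lib[j], lib[ref_i],
                    trim_m, trim_a), numeric(1))
  f / exp(mean(log(f)))
}

nb_toy_counts <- function(n_genes = 200L, n_samples = 4L, seed = 21L) {
  set.seed(seed)
  mu <- exp(runif(n_genes, log(10), log(400)))
  depth <- runif(n_samples, 0.7, 1.4)
  cts <- sapply(depth, function(d)
    rnbinom(n_genes, size = 5, mu = mu * d))
  dimnames(cts) <- list(sprintf("g%03d", 1:n_genes),
                        sprintf("s%d", 1:n_samples))
  cts
}

test_that("CPM filtering applies the mean-CPM rule and its variants", {
  cts <- rbind(lowgene = c(0L, 1L, 0L),
               kept = c(2L, 2L, 2L),
               big = c(1000L, 1000L, 1000L))
  # pad library sizes to exactly 1e6 with a filler gene
  filler <- 1e6 - colSums(cts)
  cts <- rbind(cts, filler = as.integer(filler))
  colnames(cts) <- paste0("s", 1:3)
  se <- makeCountSE(cts, condition = rep("A", 3))
  out <- cpmFilter(se, cpm_threshold = 1)
  expect_false("lowgene" %in% rownames(out))   # mean CPM 1/3 < 1
  expect_true("kept" %in% rownames(out))       # mean CPM 2 >= 1
  expect_equal(S4Vectors::metadata(out)$preprocess$cpm_removed, 1L)

  # per-sample variant keeps a gene over the threshold in >= k samples
  out2 <- cpmFilter(se, cpm_threshold = 1, min_samples_over_cpm = 1L)
  expect_true("lowgene" %in% rownames(out2))
  expect_error(cpmFilter(se, cpm_threshold = 1e9), "removed every gene")
})

test_that("CPM filtering on a toy matches direct CPM computation and is idempotent", {
  cts <- nb_toy_counts(10L, 3L, seed = 4L)
  cts[1:3, ] <- 0L  # push 3 genes below any threshold
  se <- makeCountSE(cts, condition = rep("A", 3))
  out <- cpmFilter(se, 1)
  lib <- colSums(cts)
  keep_oracle <- rowMeans(t(t(cts) / lib) * 1e6) >= 1
  expect_identical(rownames(out), rownames(cts)[keep_oracle])
  expect_equal(nrow(out), 7L)
  twice <- cpmFilter(out, 1)
  expect_identical(SummarizedExperiment::assay(twice, "counts"),
                   SummarizedExperiment::assay(out, "counts"))
})

test_that("TMM factors are unity for identical or depth-scaled samples", {
  cts <- nb_toy_counts(300L, 2L, seed = 5L)
  cts[, 2] <- cts[, 1]
  se <- makeCountSE(cts, condition = c("A", "A"))
  expect_equal(unname(tmmFactors(se)), c(1, 1))
  cts2 <- cbind(s1 = cts[, 1], s2 = 2L * cts[, 1])
  se2 <- makeCountSE(cts2, condition = c("A", "A"))
  expect_equal(unname(tmmFactors(se2)), c(1, 1))
})

test_that("TMM factors match the literal weighted-trimmed-mean oracle", {
  cts <- nb_toy_counts(400L, 4L, seed = 42L)
  se <- makeCountSE(cts, condition = rep("A", 4))
  f <- tmmFactors(se)
  expect_equal(unname(f), unname(oracle_tmm(cts)), tolerance = 1e-8)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("TMM factors of other samples are invariant to one sample's depth", {
  cts <- nb_toy_counts(400L, 5L, seed = 8L)
  se1 <- makeCountSE(cts, condition = rep("A", 5))
  f1 <- tmmFactors(se1, ref_sample = "s1")
  cts2 <- cts
  cts2[, 3] <- cts2[, 3] * 4L
  se2 <- makeCountSE(cts2, condition = rep("A", 5))
  f2 <- tmmFactors(se2, ref_sample = "s1")
  ratio <- f1[-3] / f2[-3]
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-8)
})

test_that("normalization follows the CPM / length-adjustment formula", {
  cts <- nb_toy_counts(50L, 3L, seed = 3L)
  lens <- rep(2000, 50)
  se <- makeCountSE(cts, condition = rep("A", 3), gene_lengths = lens)
  f <- setNames(c(1, 1, 1), colnames(cts))
  norm <- normalizeCounts(se, f)
  lib <- colSums(cts)
  expect_equal(SummarizedExperiment::assay(norm, "normexpr"),
               t(t(cts) / lib) * 1e6)
  # doubling a gene's length halves its length-adjusted value
  lens2 <- lens; lens2[7] <- 2 * lens2[7]
  se2 <- makeCountSE(cts, condition = rep("A", 3), gene_lengths = lens2)
  n1 <- normalizeCounts(se, f, use_lengths = TRUE)
  n2 <- normalizeCounts(se2, f, use_lengths = TRUE)
  expect_equal(SummarizedExperiment::assay(n2, "normexpr")[7, ],
               SummarizedExperiment::assay(n1, "normexpr")[7, ] / 2)
  se3 <- makeCountSE(cts, condition = rep("A", 3))
  expect_error(normalizeCounts(se3, f, use_lengths = TRUE), "gene_length")
})

test_that("stratification partitions samples exactly and preserves counts", {
  cts <- nb_toy_counts(30L, 6L, seed = 6L)
  se <- makeCountSE(cts, condition = rep(c("AD", "CT"), each = 3))
  parts <- stratifyByCondition(se)
  expect_named(parts, c("AD", "CT"))
  expect_equal(ncol(parts$AD), 3L)
  expect_identical(rownames(parts$AD), rownames(parts$CT))
  expect_setequal(c(colnames(parts$AD), colnames(parts$CT)), colnames(se))
  expect_equal(sum(SummarizedExperiment::assay(parts$AD, "counts")) +
                 sum(SummarizedExperiment::assay(parts$CT, "counts")),
               sum(cts))
  expect_error(stratifyByCondition(se, conditions = c("AD", "XX")),
               "unknown condition")
  one <- stratifyByCondition(se, conditions = "AD")
  expect_length(one, 1L)
})
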