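# Shared small synthetic fixture, generated once per test run.

small_design <- function(seed = 1L, rho = 0.8, rearrangement = 0.2) {
  syntheticDesign(n_genes = 120L, n_samples_a = 40L, n_samples_b = 40L,
                  modules_a = list(1:25, 26:50, 51:75),
                  rearrangement_fraction = rearrangement,
                  within_module_rho = rho,
                  n_hubs_b = 2L, seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- generateTwoConditionCounts(small_design())
  .fixture_cache$sim
}

# Combined two-condition SummarizedExperiment for pipeline tests.
small_combined_se <- function() {
  sim <- small_sim()
  a <- SummarizedExperiment::assay(sim$counts_a, "counts")
  b <- SummarizedExperiment::assay(sim$counts_b, "counts")
  makeCountSE(cbind(a, b),
              condition = c(rep("A", ncol(a)), rep("B", ncol(b))))
}

toy_mi_network <- function(percentile = 99) {
  if (is.null(.fixture_cache$net)) {
    sim <- small_sim()
    disc <- discretizeExpression(sim$counts_a)
    mi <- miMatrix(disc)
    .fixture_cache$mi <- mi
    .fixture_cache$net <- thresholdByPercentile(mi, percentile)
  }
  .fixture_cache$net
}
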