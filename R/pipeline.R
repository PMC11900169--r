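#' Pipeline configuration
#'
#' Nested list of all tunable parameters with the package defaults: CPM
#' threshold 1, MI percentile 99.99, top fraction 0.10 for hubs and
#' betweenness brokers, enrichment cutoffs p <= 0.05 and q <= 0.05, ten
#' optimizer trials. Per-stage seeds are derived from the master seed so one
#' stage can be re-run without perturbing the others.
#'
#' @param seed master seed (integer).
#' @param cpm_threshold CPM filter threshold.
#' @param min_samples_over_cpm optional per-sample CPM rule switch.
#' @param use_lengths length-adjust normalized values?
#' @param discretization_method,n_bins see [discretizeExpression()].
#' @param percentile MI threshold percentile.
#' @param null_n_perm permutations for the null model (0 disables it).
#' @param top_fraction hub / betweenness fraction.
#' @param n_trials optimizer restarts.
#' @param weighted weighted map equation / modularity?
#' @param delegate community-detection delegate (`"internal"` or
#'   `"igraph"`).
#' @param p_cut,q_cut,min_term,min_module enrichment settings.
#' @param file optional YAML file; values in it override the defaults.
#' @return a named list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L,
                           cpm_threshold = 1,
                           min_samples_over_cpm = NULL,
                           use_lengths = FALSE,
                           discretization_method = "equal_frequency",
                           n_bins = NULL,
                           percentile = 99.99,
                           null_n_perm = 0L,
                           top_fraction = 0.10,
                           n_trials = 10L,
                           weighted = FALSE,
                           delegate = "internal",
                           p_cut = 0.05, q_cut = 0.05,
                           min_term = 2L, min_module = 5L,
                           file = NULL) {
  cfg <- list(seed = as.integer(seed),
              preprocess = list(cpm_threshold = cpm_threshold,
                                min_samples_over_cpm = min_samples_over_cpm,
                                use_lengths = use_lengths),
              discretization = list(method = discretization_method,
                                    n_bins = n_bins),
              network = list(percentile = percentile),
              null = list(n_permutations = as.integer(null_n_perm)),
              topology = list(top_fraction = top_fraction),
              communities = list(n_trials = as.integer(n_trials),
                                 weighted = weighted,
                                 delegate = delegate),
              enrichment = list(p_cut = p_cut, q_cut = q_cut,
                                min_term = as.integer(min_term),
                                min_module = as.integer(min_module)))
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    cfg <- utils::modifyList(cfg, user)
  }
  if (cfg$network$percentile <= 0 || cfg$network$percentile >= 100)
    stop("percentile must lie in (0, 100)", call. = FALSE)
  if (cfg$topology$top_fraction <= 0 || cfg$topology$top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)", call. = FALSE)
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' Run the full differential co-expression analysis
#'
#' Executes preprocess (CPM filter, TMM, normalize, stratify), then per
#' condition MI network inference, topology, community detection, and — when
#' annotations are supplied — enrichment, and assembles a machine-readable
#' comparison report. Every numeric in the report is recomputed from the
#' persisted artifacts when `outdir` is given. Identical inputs, config and
#' seed give an identical report.
#'
#' @param se SummarizedExperiment with assay `"counts"` and a two-level
#'   `colData()$condition`.
#' @param annotations optional [AnnotationSet-class]; when `NULL` the
#'   enrichment fields are `NULL` with a reason.
#' @param config a [pipelineConfig()] list.
#' @param outdir optional output directory for artifacts (edge lists,
#'   partitions, GraphML, `report.json`). Refuses to overwrite an existing
#'   non-empty directory unless `force`.
#' @param force overwrite an existing outdir?
#' @return the comparison report (nested list); also written as
#'   `report.json` under `outdir` when given.
#' @export
runPipeline <- function(se, annotations = NULL, config = pipelineConfig(),
                        outdir = NULL, force = FALSE) {
  if (!is.null(outdir)) {
    if (dir.exists(outdir) && length(list.files(outdir)) && !force)
      stop("outdir exists and is not empty; use force = TRUE", call. = FALSE)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  conds <- unique(SummarizedExperiment::colData(se)$condition)
  if (length(conds) != 2L)
    stop("expected exactly 2 conditions, got ", length(conds), call. = FALSE)

  filtered <- stage("preprocess", cpmFilter(
    se, cpm_threshold = config$preprocess$cpm_threshold,
    min_samples_over_cpm = config$preprocess$min_samples_over_cpm))
  factors <- stage("preprocess", tmmFactors(filtered))
  norm <- stage("preprocess", normalizeCounts(
    filtered, factors, use_lengths = config$preprocess$use_lengths))
  strata <- stage("preprocess", stratifyByCondition(norm))

  per_cond <- lapply(conds, function(cc) {
    x <- strata[[cc]]
    disc <- stage("network", discretizeExpression(
      x, method = config$discretization$method,
      n_bins = config$discretization$n_bins))
    mi <- stage("network", miMatrix(disc))
    net <- stage("network",
                 thresholdByPercentile(mi, config$network$percentile))
    nullrep <- if (config$null$n_permutations >= 10L)
      stage("null", permutationNull(
        disc, n_perm = config$null$n_permutations,
        percentile = config$network$percentile,
        seed = stageSeed(config$seed, paste0("null_", cc)))) else NULL
    topo <- stage("topology", {
      ds <- degreeSummary(net)
      gamma <- tryCatch(fitGammaLogLog(ds), error = function(e) NA_real_)
      dc <- diameterComponents(net)
      cent <- centralityTable(net, config$topology$top_fraction)
      list(degree_summary = ds, gamma = gamma, diameter = dc,
           centrality = cent,
           transitivity = graphTransitivity(net),
           assortativity = tryCatch(degreeAssortativity(net),
                                    error = function(e) NA_real_))
    })
    part <- stage("communities", infomapPartition(
      net, n_trials = config$communities$n_trials,
      seed = stageSeed(config$seed, paste0("communities_", cc)),
      weighted = config$communities$weighted,
      delegate = config$communities$delegate))
    enr <- if (!is.null(annotations))
      stage("enrichment", moduleEnrichment(
        part, annotations, min_module = config$enrichment$min_module,
        p_cut = config$enrichment$p_cut, q_cut = config$enrichment$q_cut,
        min_term = config$enrichment$min_term)) else NULL
    list(condition = cc, network = net, null = nullrep, topo = topo,
         partition = part, enrichment = enr)
  })
  names(per_cond) <- conds

  a <- per_cond[[1]]
  b <- per_cond[[2]]
  cross <- stage("comparison", {
    hubs_a <- a$topo$centrality$gene[a$topo$centrality$is_hub]
    hubs_b <- b$topo$centrality$gene[b$topo$centrality$is_hub]
    btw_a <- a$topo$centrality$gene[a$topo$centrality$is_high_betweenness]
    btw_b <- b$topo$centrality$gene[b$topo$centrality$is_high_betweenness]
    sim <- membershipSimilarity(a$partition, b$partition)
    ks <- ksDegreeTest(a$topo$degree_summary$degree,
                       b$topo$degree_summary$degree)
    list(edge_jaccard = edgeJaccard(a$network, b$network),
         ks_D = ks$D, ks_p = ks$p_value,
         nmi = as.numeric(partitionNMI(a$partition, b$partition)),
         hub_overlap = compareGeneSets(hubs_a, hubs_b),
         betweenness_overlap = compareGeneSets(btw_a, btw_b),
         preservation_counts = as.list(sim@preservation),
         membership_similarity = sim)
  })

  representation <- NULL
  representation_reason <- NULL
  functional_sim <- NULL
  if (!is.null(annotations)) {
    representation <- stage("enrichment",
                            processRepresentation(a$enrichment, b$enrichment))
    functional_sim <- stage("enrichment",
                            functionalSimilarity(a$enrichment, b$enrichment))
  } else {
    representation_reason <- "annotations missing"
  }

  cond_report <- function(x) {
    list(condition = x$condition,
         n_nodes = igraph::vcount(asIgraph(x$network)),
         n_edges = igraph::ecount(asIgraph(x$network)),
         threshold_mi = thresholdValue(x$network),
         diameter = x$topo$diameter$diameter,
         n_components = x$topo$diameter$n_components,
         largest_component = x$topo$diameter$largest_component,
         transitivity = x$topo$transitivity,
         gamma = x$topo$gamma,
         assortativity = x$topo$assortativity,
         n_modules = x$partition@nModules,
         modularity_q = x$partition@modularityQ,
         map_equation_bits = x$partition@codelength,
         n_hubs = sum(x$topo$centrality$is_hub),
         n_high_betweenness = sum(x$topo$centrality$is_high_betweenness),
         null_p = if (is.null(x$null)) NULL else x$null$p_value)
  }

  report <- list(
    schema_version = "1.0",
    conditions = lapply(per_cond, cond_report),
    cross = list(edge_jaccard = cross$edge_jaccard,
                 ks_D = cross$ks_D, ks_p = cross$ks_p,
                 nmi = cross$nmi,
                 hub_overlap = cross$hub_overlap[c(
                   "n_shared", "n_a_only", "n_b_only", "n_union",
                   "pct_shared", "pct_a_only", "pct_b_only")],
                 betweenness_overlap = cross$betweenness_overlap[c(
                   "n_shared", "n_a_only", "n_b_only", "n_union",
                   "pct_shared", "pct_a_only", "pct_b_only")],
                 preservation_counts = cross$preservation_counts),
    enrichment = if (is.null(annotations))
      list(value = NULL, reason = representation_reason)
    else list(
      representation_top = representation$top,
      mean_functional_similarity =
        mean(functional_sim, na.rm = TRUE)),
    provenance = list(package_version =
                        as.character(utils::packageVersion("micoexdiff")),
                      seed = config$seed,
                      config_hash = objectHash(unclass(config))))

  if (!is.null(outdir)) {
    for (x in per_cond) {
      tag <- x$condition
      writeEdgeList(x$network, file.path(outdir, paste0("edges_", tag, ".tsv")))
      writeGraphML(x$network, file.path(outdir, paste0("network_", tag, ".graphml")))
      writePartition(x$partition, file.path(outdir, paste0("partition_", tag, ".tsv")))
      utils::write.table(x$topo$centrality,
                         file.path(outdir, paste0("centrality_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
      as.data.frame(cross$membership_similarity@jaccard),
      file.path(outdir, "module_similarity.tsv"),
      sep = "\t", quote = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  report
}
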