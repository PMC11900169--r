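#' Hypergeometric over-representation analysis
#'
#' For each term, the upper-tail hypergeometric probability
#' \eqn{p = P(X \ge n_{overlap})} with
#' \eqn{X \sim Hypergeom(N = |universe|, K = n_{term}, n = |query|)},
#' followed by Benjamini-Hochberg adjustment over all tested terms. Query
#' genes outside the universe are dropped with a warning. The full table is
#' returned; rows passing both cutoffs are flagged in the `significant`
#' column.
#'
#' @param query character vector of gene ids.
#' @param annotations an [AnnotationSet-class].
#' @param p_cut,q_cut significance cutoffs (default 0.05 each, applied
#'   jointly).
#' @param min_term smallest term size (within the universe) tested.
#' @return data.frame with columns `term`, `description`, `n_query`,
#'   `n_term`, `n_overlap`, `n_universe`, `p`, `q`, `overlap_genes`,
#'   `significant`; cutoffs are stored in `attr(, "thresholds")`.
#' @export
hypergeomORA <- function(query, annotations, p_cut = 0.05, q_cut = 0.05,
                         min_term = 2L) {
  universe <- annotations@universe
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("query is empty", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  term_genes <- lapply(annotations@terms, intersect, y = universe)
  keep <- lengths(term_genes) >= min_term
  term_genes <- term_genes[keep]
  rows <- lapply(names(term_genes), function(id) {
    tg <- term_genes[[id]]
    K <- length(tg)
    ov <- intersect(query, tg)
    p <- stats::phyper(length(ov) - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = id,
               description = unname(annotations@descriptions[id]),
               n_query = n, n_term = K, n_overlap = length(ov),
               n_universe = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    stop("no terms of size >= ", min_term, " within the universe",
         call. = FALSE)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$p <= p_cut & tab$q <= q_cut
  tab <- tab[order(tab$p, tab$term),
             c("term", "description", "n_query", "n_term", "n_overlap",
               "n_universe", "p", "q", "overlap_genes", "significant")]
  rownames(tab) <- NULL
  attr(tab, "thresholds") <- c(p_cut = p_cut, q_cut = q_cut)
  tab
}

#' Per-module over-representation
#'
#' Runs [hypergeomORA()] for every module of at least `min_module` genes.
#' The background universe is the annotation set's universe — by default all
#' genes of the analyzed (post-filter) expression matrix rather than only
#' network nodes, since network membership is itself outcome-dependent.
#'
#' @param partition a [GenePartition-class] or named membership vector.
#' @param annotations an [AnnotationSet-class].
#' @param min_module smallest module tested (default 5).
#' @param ... passed to [hypergeomORA()].
#' @return named list of enrichment tables (one per tested module); skipped
#'   modules are recorded in `attr(, "skipped")`.
#' @export
moduleEnrichment <- function(partition, annotations, min_module = 5L, ...) {
  memb <- if (methods::is(partition, "GenePartition"))
    partition@membership else partition
  mods <- split(names(memb), memb)
  sizes <- lengths(mods)
  tested <- mods[sizes >= min_module]
  out <- lapply(tested, function(genes)
    suppressWarnings(hypergeomORA(genes, annotations, ...)))
  names(out) <- paste0("M", names(tested))
  attr(out, "skipped") <- paste0("M", names(mods)[sizes < min_module])
  out
}

# Significant term ids of one module's enrichment table.
significantTerms <- function(tab) tab$term[tab$significant]

#' Functional similarity matrix between module enrichments
#'
#' Jaccard index between the sets of significantly enriched terms of every
#' module pair across two conditions. Modules with no enriched terms give
#' `NA` (flagged, not zero-by-convention).
#'
#' @param enrich_a,enrich_b outputs of [moduleEnrichment()] from the same
#'   annotation source.
#' @return numeric matrix, modules-A x modules-B.
#' @export
functionalSimilarity <- function(enrich_a, enrich_b) {
  terms_a <- lapply(enrich_a, significantTerms)
  terms_b <- lapply(enrich_b, significantTerms)
  out <- matrix(NA_real_, length(terms_a), length(terms_b),
                dimnames = list(names(terms_a), names(terms_b)))
  for (i in seq_along(terms_a)) {
    for (j in seq_along(terms_b)) {
      if (!length(terms_a[[i]]) || !length(terms_b[[j]])) next
      un <- union(terms_a[[i]], terms_b[[j]])
      out[i, j] <- length(intersect(terms_a[[i]], terms_b[[j]])) / length(un)
    }
  }
  out
}

#' Module-representation counts per term
#'
#' For every term, the number of modules enriched for it in each condition
#' and the difference table sorted by absolute difference (descending).
#'
#' @param enrich_a,enrich_b outputs of [moduleEnrichment()].
#' @param top_k rows reported in the `top` element (default 50).
#' @return list with `counts` (full data.frame `term`, `count_a`, `count_b`,
#'   `difference`) and `top` (the `top_k` largest absolute differences).
#' @export
processRepresentation <- function(enrich_a, enrich_b, top_k = 50L) {
  count_terms <- function(enr) {
    all_terms <- unlist(lapply(enr, significantTerms))
    table(all_terms)
  }
  ta <- count_terms(enrich_a)
  tb <- count_terms(enrich_b)
  terms <- sort(union(names(ta), names(tb)))
  ca <- ifelse(terms %in% names(ta), as.integer(ta[terms]), 0L)
  cb <- ifelse(terms %in% names(tb), as.integer(tb[terms]), 0L)
  df <- data.frame(term = terms, count_a = ca, count_b = cb,
                   difference = ca - cb, stringsAsFactors = FALSE)
  df <- df[order(-abs(df$difference), df$term), , drop = FALSE]
  rownames(df) <- NULL
  list(counts = df, top = utils::head(df, top_k))
}
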