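#' Build a SummarizedExperiment from a count matrix
#'
#' @param counts non-negative integer matrix, genes x samples, with unique
#'   dimnames.
#' @param condition one label per sample.
#' @param gene_lengths optional positive per-gene lengths (bp).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`.
#' @export
makeCountSE <- function(counts, condition, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts need unique gene row names", call. = FALSE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts need unique sample column names", call. = FALSE)
  if (length(condition) != ncol(counts))
    stop("one condition label per sample required", call. = FALSE)
  cd <- S4Vectors::DataFrame(condition = as.character(condition),
                             row.names = colnames(counts))
  rd <- if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != nrow(counts) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive, one per gene", call. = FALSE)
    S4Vectors::DataFrame(gene_length = as.numeric(gene_lengths),
                         row.names = rownames(counts))
  } else {
    S4Vectors::DataFrame(row.names = rownames(counts))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
}

#' Read / write count matrices
#'
#' TSV layout: genes as rows, first column `gene_id`, remaining columns one
#' per sample. MatrixMarket files are paired with `<stem>.genes.txt` and
#' `<stem>.samples.txt` sidecars. A sample-metadata TSV with columns
#' `sample_id` and `condition` supplies labels.
#'
#' @param path file to read or write.
#' @param metadata_path sample-metadata TSV (`sample_id`, `condition`).
#' @param se a SummarizedExperiment with assay `"counts"`.
#' @return `readCounts` returns a SummarizedExperiment; writers return the
#'   path invisibly.
#' @name counts-io
NULL

#' @rdname counts-io
#' @export
readCounts <- function(path, metadata_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".genes.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  condition <- rep(NA_character_, ncol(m))
  if (!is.null(metadata_path)) {
    md <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    idx <- match(colnames(m), md$sample_id)
    if (anyNA(idx)) stop("metadata missing samples: ",
                         paste(colnames(m)[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    condition <- md$condition[idx]
  }
  makeCountSE(m, condition)
}

#' @rdname counts-io
#' @export
writeCountsTSV <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts-io
#' @export
writeCountsMM <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "counts")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  stem <- sub("\\.mtx$", "", path)
  writeLines(rownames(m), paste0(stem, ".genes.txt"))
  writeLines(colnames(m), paste0(stem, ".samples.txt"))
  invisible(path)
}

#' Write synthetic ground truth as TSV
#'
#' Columns: `gene`, `module_a`, `module_b`, `is_hub_b`.
#'
#' @param truth a [GroundTruth-class].
#' @param path output TSV path.
#' @export
writeGroundTruth <- function(truth, path) {
  df <- data.frame(gene = names(truth@partitionA),
                   module_a = unname(truth@partitionA),
                   module_b = unname(truth@partitionB),
                   is_hub_b = names(truth@partitionA) %in% truth@hubGenesB)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then gene ids. The description column is preserved (it carries the
#' planted-module provenance for synthetic annotation sets).
#'
#' @param path GMT file.
#' @param universe background gene set; defaults to the union of all term
#'   genes.
#' @param annotations an [AnnotationSet-class].
#' @return `readGMT` returns an [AnnotationSet-class].
#' @name gmt-io
NULL

#' @rdname gmt-io
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("GMT lines with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- ids
  names(desc) <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  new("AnnotationSet", terms = terms, descriptions = desc,
      universe = as.character(universe))
}

#' @rdname gmt-io
#' @export
writeGMT <- function(annotations, path) {
  lines <- vapply(names(annotations@terms), function(id) {
    paste(c(id, annotations@descriptions[[id]], annotations@terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network's edge list / GraphML
#'
#' The edge list TSV has columns `gene_a`, `gene_b`, `mi`, sorted by MI
#' descending.
#'
#' @param net a [CoexNetwork-class].
#' @param path output file.
#' @name network-io
NULL

#' @rdname network-io
#' @export
writeEdgeList <- function(net, path) {
  g <- asIgraph(net)
  e <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(NA_real_, nrow(e))
  df <- data.frame(gene_a = pmin(e[, 1], e[, 2]),
                   gene_b = pmax(e[, 1], e[, 2]), mi = w)
  df <- df[order(-df$mi, df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a module partition as TSV (`gene`, `module`)
#'
#' @param partition a [GenePartition-class].
#' @param path output TSV path.
#' @export
writePartition <- function(partition, path) {
  df <- data.frame(gene = names(partition@membership),
                   module = unname(partition@membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
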