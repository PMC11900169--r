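#' Accessors for micoexdiff S4 classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("miValues", function(x) standardGeneric("miValues"))

#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname accessors
#' @export
setGeneric("moduleAssignments", function(x) standardGeneric("moduleAssignments"))

#' @rdname accessors
#' @export
setGeneric("codelength", function(x) standardGeneric("codelength"))

#' @rdname accessors
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

#' @rdname accessors
#' @export
setGeneric("annotationTerms", function(x) standardGeneric("annotationTerms"))

#' @rdname accessors
#' @export
setGeneric("annotationUniverse", function(x) standardGeneric("annotationUniverse"))

#' @rdname accessors
#' @export
setMethod("geneIds", "MIResult", function(x) rownames(x@mi))

#' @rdname accessors
#' @export
setMethod("geneIds", "CoexNetwork",
          function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setMethod("miValues", "MIResult", function(x) x@mi)

#' @rdname accessors
#' @export
setMethod("asIgraph", "CoexNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("thresholdValue", "CoexNetwork", function(x) x@thresholdValue)

#' @rdname accessors
#' @export
setMethod("moduleAssignments", "GenePartition", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("codelength", "GenePartition", function(x) x@codelength)

#' @rdname accessors
#' @export
setMethod("modularityQ", "GenePartition", function(x) x@modularityQ)

#' @rdname accessors
#' @export
setMethod("annotationTerms", "AnnotationSet", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("annotationUniverse", "AnnotationSet", function(x) x@universe)
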