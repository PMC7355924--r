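#' Accessors for SignedNetwork and ExpressionCollection
#'
#' `geneIds()` returns the ordered node (gene) vector, `edgeTable()` the
#' signed edge data.frame, `ambiguousPairs()` the ordered pairs dropped for
#' carrying both signs, and `auditLog()` the merge bookkeeping counts.
#' `signedAdjacency()` returns the sparse matrix S with S[i,j] in {-1,0,+1}
#' and `unsignedAdjacency()` its support B = |S|. For collections,
#' `datasets()` returns the SimpleList of SummarizedExperiment objects and
#' `datasetIds()` their names.
#'
#' @param x a `SignedNetwork` or `ExpressionCollection`.
#' @return See details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("ambiguousPairs", function(x) standardGeneric("ambiguousPairs"))

#' @rdname accessors
#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))

#' @rdname accessors
#' @export
setGeneric("signedAdjacency", function(x) standardGeneric("signedAdjacency"))

#' @rdname accessors
#' @export
setGeneric("unsignedAdjacency", function(x) standardGeneric("unsignedAdjacency"))

#' @rdname accessors
#' @export
setGeneric("datasets", function(x) standardGeneric("datasets"))

#' @rdname accessors
#' @export
setGeneric("datasetIds", function(x) standardGeneric("datasetIds"))
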