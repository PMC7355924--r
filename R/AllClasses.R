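#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

#' SignedNetwork: a directed signaling network with per-edge signs
#'
#' Container for a merged, signed, directed signaling network. Edges carry a
#' sign of +1 (activation) or -1 (inhibition). Ordered gene pairs that were
#' annotated with both signs in the merged inputs are, under the default
#' merge policy, excluded from the edge table and kept in the ambiguous-pair
#' table, because an unresolvable sign cannot be scored for coherency.
#'
#' Node order is lexicographic and fixed at construction so that adjacency
#' matrices and every downstream index are reproducible across runs.
#'
#' @slot nodes character vector of gene identifiers, sorted, unique.
#' @slot edges data.frame with columns `source`, `target`, `sign`
#'   (integer, +1 or -1) and `provenance` (character, possibly NA).
#' @slot ambiguousPairs data.frame with columns `source`, `target` listing
#'   ordered pairs removed because they carried both signs.
#' @slot audit named list of merge bookkeeping: `inputRows`, `selfLoops`,
#'   `duplicates`, `ambiguousRows` — used for the conservation audit
#'   edges + duplicates + selfLoops + ambiguousRows == inputRows.
#'
#' @seealso [mergeEdgeLists()], [giantComponent()], [networkMetrics()]
#' @export
setClass("SignedNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    ambiguousPairs = "data.frame",
    audit = "list"
  )
)

setValidity("SignedNetwork", function(object) {
  msg <- character()
  if (is.unsorted(object@nodes, strictly = TRUE))
    msg <- c(msg, "nodes must be strictly sorted (lexicographic, unique)")
  req <- c("source", "target", "sign")
  if (!all(req %in% names(object@edges)))
    msg <- c(msg, "edges must have columns source, target, sign")
  else {
    e <- object@edges
    if (nrow(e)) {
      if (!all(e$sign %in% c(-1L, 1L)))
        msg <- c(msg, "edge signs must be +1 or -1")
      if (any(e$source == e$target))
        msg <- c(msg, "self-loops are not permitted")
      if (!all(c(e$source, e$target) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be network nodes")
      if (anyDuplicated(paste(e$source, e$target, e$sign, sep = "\r")))
        msg <- c(msg, "duplicate (source, target, sign) rows")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ExpressionCollection: independent expression datasets plus manifest
#'
#' Holds one or more named expression datasets, each a
#' [SummarizedExperiment::SummarizedExperiment] with a single `exprs` assay
#' (genes in rows, samples in columns; platform-dependent abundance treated
#' as unitless). Datasets are analyzed separately and never pooled: sample
#' heterogeneity across studies would otherwise obscure pairwise
#' relationships.
#'
#' @slot datasets [S4Vectors::SimpleList] of SummarizedExperiment objects,
#'   uniquely named by dataset id.
#' @slot manifest data.frame of per-dataset metadata with at least an `id`
#'   column matching the dataset names.
#'
#' @seealso [readExpression()], [pairObservations()], [eligibleDatasets()]
#' @export
setClass("ExpressionCollection",
  representation(
    datasets = "SimpleList",
    manifest = "data.frame"
  )
)

setValidity("ExpressionCollection", function(object) {
  msg <- character()
  ids <- names(object@datasets)
  if (length(object@datasets)) {
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
      msg <- c(msg, "datasets must have unique non-empty names")
    ok <- vapply(object@datasets, inherits, logical(1), "SummarizedExperiment")
    if (!all(ok))
      msg <- c(msg, "every dataset must be a SummarizedExperiment")
  }
  if (nrow(object@manifest) && !"id" %in% names(object@manifest))
    msg <- c(msg, "manifest must have an `id` column")
  if (length(msg)) msg else TRUE
})
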