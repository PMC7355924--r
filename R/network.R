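#' Default sign vocabulary for edge-list parsing
#'
#' Maps the sign tokens commonly found in exported signaling edge lists to
#' integer signs: activation-type tokens to +1, inhibition-type tokens to -1.
#' Pass a modified copy to [readEdgeList()] to accept other vocabularies
#' (e.g. SIF relation types such as `"activates"`).
#'
#' @return Named integer vector mapping token to +1 / -1.
#' @export
#' @examples
#' defaultSignVocabulary()
defaultSignVocabulary <- function() {
  c("activation" = 1L, "activates" = 1L, "1" = 1L, "+1" = 1L, "+" = 1L,
    "inhibition" = -1L, "inhibits" = -1L, "-1" = -1L, "-" = -1L,
    "−" = -1L, "−1" = -1L)
}

newSignedEdgeList <- function(source, target, sign, provenance = NA_character_) {
  data.frame(source = as.character(source), target = as.character(target),
             sign = as.integer(sign),
             provenance = rep_len(as.character(provenance), length(source)),
             stringsAsFactors = FALSE)
}

#' Read a signed directed edge list
#'
#' Parses a tab-separated edge list as exported from pathway databases.
#' Two dialects are supported: `tsv3` with columns
#' `source<TAB>target<TAB>sign` (header row optional) and `sif` with columns
#' `source<TAB>relation<TAB>target`. Sign/relation tokens are translated
#' through `signVocabulary` (case-insensitive); rows with unknown tokens are
#' an error. Self-loops are dropped (the analysis is about gene *pairs*; a
#' self-loop has no pair correlation) and exact duplicate rows are collapsed
#' to a single edge; both counts are recorded in attributes so the merge
#' audit can reconcile every input row.
#'
#' @param path path to the edge-list file.
#' @param dialect `"tsv3"` (source, target, sign) or `"sif"`
#'   (source, relation, target).
#' @param signVocabulary named integer vector mapping sign tokens to +1/-1;
#'   see [defaultSignVocabulary()].
#' @param provenance optional database tag stored with every edge.
#' @return data.frame with columns `source`, `target`, `sign`, `provenance`
#'   and attributes `selfLoops` (rows dropped) and `duplicates` (rows
#'   collapsed).
#' @export
readEdgeList <- function(path, dialect = c("tsv3", "sif"),
                         signVocabulary = defaultSignVocabulary(),
                         provenance = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("edge-list file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("malformed edge-list row (expected 3 tab-separated fields) at line ",
         bad[1L], " of ", path)
  m <- do.call(rbind, fields)
  # optional header: first row matching the canonical column names
  hdr3 <- c("source", "target", "sign")
  hdrSif <- c("source", "relation", "target")
  first <- tolower(trimws(m[1L, ]))
  if (identical(first, hdr3) || identical(first, hdrSif)) {
    m <- m[-1L, , drop = FALSE]
    if (!nrow(m)) stop("edge-list file has a header but no rows: ", path)
  }
  if (dialect == "tsv3") {
    src <- trimws(m[, 1L]); tgt <- trimws(m[, 2L]); tok <- trimws(m[, 3L])
  } else {
    src <- trimws(m[, 1L]); tok <- trimws(m[, 2L]); tgt <- trimws(m[, 3L])
  }
  names(signVocabulary) <- tolower(names(signVocabulary))
  sgn <- signVocabulary[tolower(tok)]
  if (anyNA(sgn)) {
    i <- which(is.na(sgn))[1L]
    stop("unknown sign token '", tok[i], "' in ", path,
         " (line ", i, " of data); extend signVocabulary to accept it")
  }
  el <- newSignedEdgeList(src, tgt, sgn, provenance)
  nSelf <- sum(el$source == el$target)
  if (nSelf)
    message(nSelf, " self-loop row(s) dropped from ", basename(path))
  el <- el[el$source != el$target, , drop = FALSE]
  key <- paste(el$source, el$target, el$sign, sep = "\r")
  nDup <- sum(duplicated(key))
  el <- el[!duplicated(key), , drop = FALSE]
  rownames(el) <- NULL
  attr(el, "selfLoops") <- nSelf
  attr(el, "duplicates") <- nDup
  el
}

#' Merge signed edge lists into a SignedNetwork
#'
#' Concatenates one or more edge lists (see [readEdgeList()]) into a single
#' directed signed network. Self-loops are dropped and exact duplicates
#' collapsed (again, across lists). An ordered pair annotated with *both*
#' signs after the merge is handled by `conflictPolicy`:
#' \describe{
#'   \item{`"ambiguous"` (default)}{the pair is excluded from the edge table
#'     and recorded in [ambiguousPairs()]; an unresolvable sign cannot be
#'     scored for coherency.}
#'   \item{`"keep_both"`}{both signed edges are retained in the edge table
#'     (the signed adjacency entry for such a pair is the sign sum, 0).}
#'   \item{`"drop"`}{the pair is silently removed.}
#' }
#' The audit slot reconciles every input row:
#' `edges + duplicates + selfLoops + ambiguousRows == inputRows` (under
#' `"keep_both"` the conflicting rows stay in `edges`; under `"drop"` they
#' are counted in `ambiguousRows` but the pair list is empty).
#'
#' @param lists a single edge-list data.frame or a list of them.
#' @param conflictPolicy one of `"ambiguous"`, `"keep_both"`, `"drop"`.
#' @return A [SignedNetwork-class] object.
#' @export
mergeEdgeLists <- function(lists, conflictPolicy = c("ambiguous", "keep_both", "drop")) {
  conflictPolicy <- match.arg(conflictPolicy)
  if (is.data.frame(lists)) lists <- list(lists)
  if (!length(lists)) stop("at least one edge list is required")
  inputRows <- sum(vapply(lists, nrow, integer(1))) +
    sum(vapply(lists, function(l) {
      (attr(l, "selfLoops") %||% 0L) + (attr(l, "duplicates") %||% 0L)
    }, numeric(1)))
  el <- do.call(rbind, lapply(lists, function(l) {
    l[, c("source", "target", "sign",
          if ("provenance" %in% names(l)) "provenance")]
  }))
  if (is.null(el$provenance))
    el$provenance <- rep(NA_character_, nrow(el))
  nSelf <- sum(el$source == el$target) +
    sum(vapply(lists, function(l) attr(l, "selfLoops") %||% 0L, numeric(1)))
  el <- el[el$source != el$target, , drop = FALSE]
  key <- paste(el$source, el$target, el$sign, sep = "\r")
  nDup <- sum(duplicated(key)) +
    sum(vapply(lists, function(l) attr(l, "duplicates") %||% 0L, numeric(1)))
  el <- el[!duplicated(key), , drop = FALSE]

  pairKey <- paste(el$source, el$target, sep = "\r")
  conflicted <- pairKey %in% pairKey[duplicated(pairKey)]
  ambRows <- 0L
  amb <- data.frame(source = character(), target = character(),
                    stringsAsFactors = FALSE)
  if (any(conflicted) && conflictPolicy != "keep_both") {
    ambRows <- sum(conflicted)
    if (conflictPolicy == "ambiguous") {
      ap <- unique(el[conflicted, c("source", "target")])
      amb <- ap[order(ap$source, ap$target), , drop = FALSE]
      rownames(amb) <- NULL
    }
    el <- el[!conflicted, , drop = FALSE]
  }
  el <- el[order(el$source, el$target, el$sign), , drop = FALSE]
  rownames(el) <- NULL
  nodes <- sort(unique(c(el$source, el$target, amb$source, amb$target)))
  new("SignedNetwork", nodes = nodes, edges = el, ambiguousPairs = amb,
      audit = list(inputRows = inputRows, selfLoops = nSelf,
                   duplicates = nDup, ambiguousRows = ambRows,
                   conflictPolicy = conflictPolicy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname accessors
#' @export
setMethod("geneIds", "SignedNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "SignedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("ambiguousPairs", "SignedNetwork", function(x) x@ambiguousPairs)

#' @rdname accessors
#' @export
setMethod("auditLog", "SignedNetwork", function(x) x@audit)

#' @rdname accessors
#' @export
setMethod("signedAdjacency", "SignedNetwork", function(x) {
  n <- length(x@nodes)
  e <- x@edges
  i <- match(e$source, x@nodes)
  j <- match(e$target, x@nodes)
  # duplicated ordered pairs (keep_both policy) sum their signs
  Matrix::sparseMatrix(i = i, j = j, x = as.numeric(e$sign),
                       dims = c(n, n), dimnames = list(x@nodes, x@nodes))
})

#' @rdname accessors
#' @export
setMethod("unsignedAdjacency", "SignedNetwork", function(x) {
  S <- signedAdjacency(x)
  abs(sign(S))
})

setMethod("show", "SignedNetwork", function(object) {
  cat("SignedNetwork with", length(object@nodes), "genes and",
      nrow(object@edges), "signed edges\n")
  if (nrow(object@edges)) {
    tab <- table(factor(object@edges$sign, levels = c(1, -1),
                        labels = c("activation", "inhibition")))
    cat("  ", tab[["activation"]], "activation /",
        tab[["inhibition"]], "inhibition\n")
  }
  if (nrow(object@ambiguousPairs))
    cat("  ", nrow(object@ambiguousPairs), "ambiguous-sign pair(s) excluded\n")
  invisible(object)
})

asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    unique(net@edges[, c("source", "target")]),
    directed = TRUE,
    vertices = data.frame(name = net@nodes))
}

#' Restrict a network to its giant weakly connected component
#'
#' Returns the subnetwork induced by the largest weakly connected component.
#' Equal-size ties are broken in favor of the component containing the
#' lexicographically smallest gene, so the result is deterministic.
#'
#' @param net a [SignedNetwork-class].
#' @return A [SignedNetwork-class] restricted to the giant component
#'   (ambiguous pairs restricted likewise; audit carried over).
#' @export
giantComponent <- function(net) {
  stopifnot(is(net, "SignedNetwork"))
  if (!length(net@nodes)) stop("network is empty")
  g <- asIgraph(net)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component holding the lexicographically smallest member
    firstMember <- vapply(best, function(k)
      min(net@nodes[comp$membership == k]), character(1))
    best <- best[order(firstMember)[1L]]
  }
  keep <- net@nodes[comp$membership == best]
  subsetNetwork(net, keep)
}

subsetNetwork <- function(net, keep) {
  e <- net@edges
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  amb <- net@ambiguousPairs
  amb <- amb[amb$source %in% keep & amb$target %in% keep, , drop = FALSE]
  rownames(amb) <- NULL
  new("SignedNetwork", nodes = sort(keep), edges = e, ambiguousPairs = amb,
      audit = net@audit)
}

#' Structural metrics of the giant component
#'
#' Computes the giant-component size, diameter (maximum node eccentricity)
#' and radius (minimum node eccentricity). Both are computed on the
#' undirected projection by default: the diameter is used downstream as a
#' reachability horizon, and the undirected projection gives the maximal
#' (safest) horizon; set `mode = "directed"` for directed eccentricities.
#'
#' @param net a [SignedNetwork-class]; reduced to its giant component first.
#' @param mode `"undirected"` (default) or `"directed"`.
#' @return list with `giantSize`, `diameter`, `radius`.
#' @export
networkMetrics <- function(net, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  gc <- giantComponent(net)
  if (length(gc@nodes) < 2L)
    stop("giant component has fewer than 2 nodes; metrics undefined")
  g <- asIgraph(gc)
  eccMode <- if (mode == "undirected") "all" else "out"
  ecc <- igraph::eccentricity(g, mode = eccMode)
  list(giantSize = length(gc@nodes),
       diameter = as.integer(max(ecc)),
       radius = as.integer(min(ecc)))
}

#' Export a merged network as TSV files
#'
#' Writes the 3-column edge list (`source`, `target`, `sign`, with signs as
#' `activation`/`inhibition`) and, if present, a companion ambiguous-pairs
#' TSV next to it.
#'
#' @param net a [SignedNetwork-class].
#' @param path output path for the edge list TSV.
#' @param ambiguousPath optional output path for the ambiguous pairs; default
#'   is `path` with an `.ambiguous.tsv` suffix. Only written when ambiguous
#'   pairs exist.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path, ambiguousPath = NULL) {
  e <- net@edges
  out <- data.frame(source = e$source, target = e$target,
                    sign = ifelse(e$sign > 0, "activation", "inhibition"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(net@ambiguousPairs)) {
    if (is.null(ambiguousPath))
      ambiguousPath <- sub("(\\.tsv)?$", ".ambiguous.tsv", path)
    utils::write.table(net@ambiguousPairs, ambiguousPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
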