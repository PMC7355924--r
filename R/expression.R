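#' Read one expression dataset from TSV
#'
#' Loads a genes-by-samples expression matrix. The first column must be the
#' gene identifier; remaining columns are samples. Non-numeric cells become
#' missing values. Duplicate gene rows are an error (collapse probes to genes
#' upstream of this tool).
#'
#' @param path TSV file, first column `gene`, remaining columns sample ids.
#' @param datasetId dataset identifier stored in the object metadata.
#' @param log2Transform if TRUE, apply log2(x + 1) to all values. Default
#'   FALSE: values are used as provided, preprocessing is upstream.
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay
#'   `exprs`.
#' @export
readExpression <- function(path, datasetId, log2Transform = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression matrix needs >= 1 sample column: ", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"   # non-numeric cells -> NA with a coercion warning
  rownames(m) <- genes
  if (!nrow(m) || !ncol(m)) stop("empty expression matrix: ", path)
  if (log2Transform) m <- log2(m + 1)
  makeExpressionDataset(m, datasetId)
}

makeExpressionDataset <- function(m, datasetId) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    metadata = list(datasetId = datasetId))
}

#' Construct an ExpressionCollection
#'
#' @param datasets named list of SummarizedExperiment objects (names are the
#'   dataset ids) or plain numeric matrices (genes x samples), which are
#'   wrapped.
#' @param manifest optional data.frame of per-dataset metadata with an `id`
#'   column; defaults to a minimal manifest built from the names.
#' @return An [ExpressionCollection-class].
#' @export
ExpressionCollection <- function(datasets, manifest = NULL) {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be a named list")
  datasets <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (is.matrix(d)) makeExpressionDataset(d, names(datasets)[i]) else d
  }) |> stats::setNames(names(datasets))
  if (is.null(manifest))
    manifest <- data.frame(id = names(datasets), stringsAsFactors = FALSE)
  new("ExpressionCollection", datasets = S4Vectors::SimpleList(datasets),
      manifest = manifest)
}

#' Read an expression manifest and load all datasets
#'
#' The manifest is a YAML or JSON list of entries `{id, path, tags...}`;
#' paths are resolved relative to the manifest file.
#'
#' @param path manifest file (.yaml/.yml/.json).
#' @param log2Transform passed to [readExpression()].
#' @return An [ExpressionCollection-class].
#' @export
readExpressionManifest <- function(path, log2Transform = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!length(entries)) stop("manifest is empty: ", path)
  base <- dirname(path)
  ds <- list()
  meta <- list()
  for (e in entries) {
    if (is.null(e$id) || is.null(e$path))
      stop("manifest entries need `id` and `path`")
    p <- if (file.exists(e$path)) e$path else file.path(base, e$path)
    ds[[e$id]] <- readExpression(p, e$id, log2Transform)
    meta[[e$id]] <- data.frame(
      id = e$id,
      tags = paste(unlist(e[setdiff(names(e), c("id", "path"))]),
                   collapse = ";"),
      stringsAsFactors = FALSE)
  }
  ExpressionCollection(ds, manifest = do.call(rbind, meta))
}

#' Read DEG labels
#'
#' Two-column TSV `gene<TAB>direction` with direction `up` or `down`,
#' emulating database-flagged differentially expressed genes. Each gene must
#' carry exactly one direction.
#'
#' @param path TSV file; a `gene`/`direction` header row is optional.
#' @return Named character vector mapping gene id to `"up"`/`"down"`.
#' @export
readDegLabels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("DEG label file must have 2 columns: ", path)
  if (tolower(df[1, 1]) == "gene") df <- df[-1L, , drop = FALSE]
  dir <- tolower(trimws(df[[2L]]))
  if (!all(dir %in% c("up", "down")))
    stop("DEG direction must be 'up' or 'down'")
  gene <- as.character(df[[1L]])
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    conflicting <- vapply(dup, function(g)
      length(unique(dir[gene == g])) > 1L, logical(1))
    if (any(conflicting))
      stop("gene(s) labeled with both directions: ",
           paste(dup[conflicting], collapse = ", "))
    keep <- !duplicated(gene)
    gene <- gene[keep]; dir <- dir[keep]
  }
  stats::setNames(dir, gene)
}

#' @rdname accessors
#' @export
setMethod("datasets", "ExpressionCollection", function(x) x@datasets)

#' @rdname accessors
#' @export
setMethod("datasetIds", "ExpressionCollection", function(x) names(x@datasets))

setMethod("show", "ExpressionCollection", function(object) {
  cat("ExpressionCollection with", length(object@datasets), "dataset(s)\n")
  for (id in names(object@datasets)) {
    d <- object@datasets[[id]]
    cat(sprintf("  %s: %d genes x %d samples\n", id, nrow(d), ncol(d)))
  }
  invisible(object)
})

exprsMatrix <- function(ds) SummarizedExperiment::assay(ds, "exprs")

#' Paired complete-case observations for a gene pair in one dataset
#'
#' Aligns the expression vectors of two genes on shared samples and drops
#' samples missing either gene (correlation needs paired observations).
#' Returns NULL ("absent") when either gene is not measured in the dataset.
#'
#' @param geneI,geneII gene identifiers (opaque, case-sensitive strings).
#' @param ds a SummarizedExperiment dataset (one element of
#'   [datasets()]).
#' @return list with `dataset`, `x` (gene I values), `y` (gene II values) and
#'   `n`, or NULL if either gene is absent.
#' @export
pairObservations <- function(geneI, geneII, ds) {
  m <- exprsMatrix(ds)
  if (!(geneI %in% rownames(m)) || !(geneII %in% rownames(m)))
    return(NULL)
  x <- m[geneI, ]
  y <- m[geneII, ]
  ok <- !is.na(x) & !is.na(y)
  list(dataset = S4Vectors::metadata(ds)$datasetId %||% NA_character_,
       x = unname(x[ok]), y = unname(y[ok]), n = sum(ok))
}

#' Eligible per-dataset observations for a gene pair
#'
#' A dataset contributes to a pair when both genes are measured and more
#' than two complete-case samples remain (`n >= minN`, default 3). A pair is
#' *eligible* when at least one dataset contributes. Eligibility is assessed
#' per dataset, never by pooling samples across datasets.
#'
#' @param geneI,geneII gene identifiers.
#' @param coll an [ExpressionCollection-class].
#' @param minN minimum paired sample count per dataset; must be >= 3.
#' @return list of paired-vector lists (see [pairObservations()]), possibly
#'   empty.
#' @export
eligibleDatasets <- function(geneI, geneII, coll, minN = 3L) {
  if (minN < 3L)
    stop("minN must be >= 3: correlation needs more than two samples")
  out <- list()
  for (id in datasetIds(coll)) {
    pv <- pairObservations(geneI, geneII, coll@datasets[[id]])
    if (!is.null(pv) && pv$n >= minN) {
      pv$dataset <- id
      out[[length(out) + 1L]] <- pv
    }
  }
  out
}

#' Ratio of expression-eligible edges
#'
#' Fraction of the network's simple edges whose gene pair is eligible (at
#' least one dataset with more than two paired samples).
#'
#' @param net a [SignedNetwork-class].
#' @param coll an [ExpressionCollection-class].
#' @param minN per-dataset eligibility threshold, see [eligibleDatasets()].
#' @return list with `nEdges`, `nEligible`, `ratio`.
#' @export
eligibleEdgeRatio <- function(net, coll, minN = 3L) {
  e <- unique(edgeTable(net)[, c("source", "target")])
  elig <- eligiblePairMask(e$source, e$target, coll, minN)
  list(nEdges = nrow(e), nEligible = sum(elig),
       ratio = if (nrow(e)) sum(elig) / nrow(e) else NA_real_)
}

# Vectorized eligibility for many pairs: per dataset, count samples where
# both genes are observed, via crossproduct of the non-missing indicator.
eligiblePairMask <- function(genesI, genesII, coll, minN = 3L) {
  stopifnot(length(genesI) == length(genesII))
  elig <- logical(length(genesI))
  for (id in datasetIds(coll)) {
    m <- exprsMatrix(coll@datasets[[id]])
    hasI <- genesI %in% rownames(m)
    hasII <- genesII %in% rownames(m)
    cand <- which(hasI & hasII & !elig)
    if (!length(cand)) next
    P <- !is.na(m)
    cnt <- rowSums(P[genesI[cand], , drop = FALSE] &
                   P[genesII[cand], , drop = FALSE])
    elig[cand[cnt >= minN]] <- TRUE
  }
  elig
}
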