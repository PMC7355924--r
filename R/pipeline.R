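#' Run configuration for the end-to-end coherency pipeline
#'
#' Collects every tunable of the analysis in one list. Inputs can be given
#' as file paths (`edgeLists`, a character vector of signed edge-list TSVs;
#' `expressionManifest`, a YAML/JSON manifest) or as in-memory objects
#' (`network`, `expression`), which take precedence.
#'
#' @param edgeLists character vector of edge-list paths.
#' @param expressionManifest manifest path, see [readExpressionManifest()].
#' @param network optional [SignedNetwork-class] (skips edge-list loading).
#' @param expression optional [ExpressionCollection-class].
#' @param method correlation method.
#' @param minN per-dataset eligibility threshold (>= 3).
#' @param alpha adjusted-p significance cutoff.
#' @param aggregate per-dataset aggregation policy, see [assessPair()].
#' @param conflictPolicy merge policy, see [mergeEdgeLists()].
#' @param ugpM,ugpR unconnected-pair replicate design (default 1000 x 10).
#' @param seed master seed for UGP sampling.
#' @param proportion which proportion the class comparisons test.
#' @param outputDir optional directory for the report bundle.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(edgeLists = NULL, expressionManifest = NULL,
                      network = NULL, expression = NULL,
                      method = c("pearson", "spearman", "kendall"),
                      minN = 3L, alpha = 0.05,
                      aggregate = c("weighted", "max_n"),
                      conflictPolicy = c("ambiguous", "keep_both", "drop"),
                      ugpM = 1000L, ugpR = 10L, seed = 1L,
                      proportion = c("positive", "negative", "coherent"),
                      outputDir = NULL) {
  cfg <- list(edgeLists = edgeLists, expressionManifest = expressionManifest,
              network = network, expression = expression,
              method = match.arg(method), minN = as.integer(minN),
              alpha = alpha, aggregate = match.arg(aggregate),
              conflictPolicy = match.arg(conflictPolicy),
              ugpM = as.integer(ugpM), ugpR = as.integer(ugpR),
              seed = as.integer(seed), proportion = match.arg(proportion),
              outputDir = outputDir)
  class(cfg) <- "runConfig"
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads the config keys of [runConfig()] from a YAML file; relative paths
#' are resolved against the file's directory.
#'
#' @param path YAML file.
#' @return list of class `"runConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  if (!is.null(y$edgeLists)) y$edgeLists <- resolve(unlist(y$edgeLists))
  if (!is.null(y$expressionManifest))
    y$expressionManifest <- resolve(y$expressionManifest)
  if (!is.null(y$outputDir) && !dir.exists(y$outputDir))
    y$outputDir <- file.path(base, y$outputDir)
  do.call(runConfig, y)
}

#' Run the coherency analysis end to end
#'
#' Executes the whole chain: network load/merge, giant component and
#' metrics, per-edge correlation across datasets with homogeneity filtering,
#' one Benjamini-Hochberg family over the run's scorable edges, sign and
#' coherency classification, subgraph census at the network radius,
#' unconnected-gene-pair sampling at horizon diameter + 1 (classified in
#' their own BH family), the per-class ratio table, and all pairwise
#' class-proportion tests. With `cfg$outputDir` set, writes
#' `pair_associations.tsv`, `census.tsv`, `ugp_pairs.tsv`,
#' `ratio_table.tsv`, `proportion_tests.tsv` and `run_summary.json`
#' (counts at each filter stage, seed, policies). Outputs contain no
#' timestamps, so a fixed config and seed reproduce them byte for byte.
#'
#' The filter funnel over simple edges is conserved exactly:
#' `total = ineligible + heterogeneous + coherent + incoherent +
#' non_significant` (pairs whose eligible datasets are all
#' degenerate/constant are counted as ineligible).
#'
#' @param cfg a [runConfig()] or path to a YAML config.
#' @return list with `network`, `giant`, `metrics`, `edgeAssociations`,
#'   `census`, `ugpPairs`, `ugpAssociations`, `ratioTable`,
#'   `proportionTests`, `funnel`, `summary` (invisibly returns file paths in
#'   `files` when written).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "runConfig"))

  net <- cfg$network
  if (is.null(net)) {
    if (is.null(cfg$edgeLists))
      stop("pipeline stage 'network': no network or edgeLists supplied")
    lists <- lapply(cfg$edgeLists, function(p) {
      if (!file.exists(p))
        stop("pipeline stage 'network': edge list not found: ", p)
      readEdgeList(p, provenance = basename(p))
    })
    net <- mergeEdgeLists(lists, conflictPolicy = cfg$conflictPolicy)
  }
  coll <- cfg$expression
  if (is.null(coll)) {
    if (is.null(cfg$expressionManifest))
      stop("pipeline stage 'expression': no collection or manifest supplied")
    coll <- readExpressionManifest(cfg$expressionManifest)
  }

  gc <- giantComponent(net)
  metrics <- networkMetrics(gc)

  edgeAssoc <- associateEdges(net, coll, method = cfg$method,
                              minN = cfg$minN, alpha = cfg$alpha,
                              aggregate = cfg$aggregate)
  funnel <- funnelCounts(edgeAssoc)

  census <- censusAll(gc, radius = metrics$radius)
  classifiedCensus <- joinCensusCategories(census, edgeAssoc)

  ugpPairs <- sampleUGP(gc, coll, m = cfg$ugpM, R = cfg$ugpR,
                        seed = cfg$seed, minN = cfg$minN)
  uniq <- unique(ugpPairs[, c("geneI", "geneII")])
  ugpAssocU <- associatePairs(uniq, coll, method = cfg$method,
                              minN = cfg$minN, alpha = cfg$alpha,
                              aggregate = cfg$aggregate)
  keyU <- paste(ugpAssocU$geneI, ugpAssocU$geneII, sep = "\r")
  keyR <- paste(ugpPairs$geneI, ugpPairs$geneII, sep = "\r")
  ugpAssoc <- cbind(ugpPairs,
                    ugpAssocU[match(keyR, keyU),
                              c("n_datasets", "combined_r", "combined_p",
                                "q", "homogeneous", "status", "category")])
  rownames(ugpAssoc) <- NULL
  ugpClassified <- data.frame(class = "UGP",
                              replicate = ugpAssoc$replicate,
                              category = ugpAssoc$category,
                              coherency_call = NA_character_,
                              stringsAsFactors = FALSE)

  allClasses <- c("Act", "Inh", "DNFBL", "DPFBL1", "DPFBL2",
                  "MNFBL1", "MPFBL1", "MNFBL2", "MPFBL2",
                  "MFFL1", "MFFL2", "MNFFL1", "MNFFL2", "UGP")
  classified <- rbind(
    classifiedCensus[, c("class", "category", "coherency_call")]
      |> transform(replicate = NA_integer_),
    ugpClassified[, c("class", "category", "coherency_call", "replicate")])
  ratioTable <- buildRatioTable(classified,
                                classes = intersect(allClasses,
                                                    unique(classified$class)))
  proportionTests <- compareAllClasses(ratioTable,
                                       proportion = cfg$proportion)

  summary <- list(
    nGenes = length(geneIds(net)),
    nEdges = nrow(edgeTable(net)),
    nAmbiguousPairs = nrow(ambiguousPairs(net)),
    audit = auditLog(net)[c("inputRows", "selfLoops", "duplicates",
                            "ambiguousRows")],
    giantSize = metrics$giantSize,
    diameter = metrics$diameter,
    radius = metrics$radius,
    funnel = funnel,
    nCensusAssignments = nrow(census),
    ugp = list(m = cfg$ugpM, R = cfg$ugpR, seed = cfg$seed),
    policies = list(method = cfg$method, minN = cfg$minN, alpha = cfg$alpha,
                    aggregate = cfg$aggregate,
                    conflictPolicy = cfg$conflictPolicy,
                    proportion = cfg$proportion))

  res <- list(network = net, giant = gc, metrics = metrics,
              edgeAssociations = edgeAssoc, census = census,
              ugpPairs = ugpPairs, ugpAssociations = ugpAssoc,
              ratioTable = ratioTable, proportionTests = proportionTests,
              funnel = funnel, summary = summary)

  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) {
      p <- file.path(cfg$outputDir, f)
      utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    files <- c(
      pairAssociations = wt(edgeAssoc, "pair_associations.tsv"),
      census = wt(census, "census.tsv"),
      ugpPairs = wt(ugpAssoc, "ugp_pairs.tsv"),
      ratioTable = wt(ratioTable, "ratio_table.tsv"),
      proportionTests = wt(proportionTests, "proportion_tests.tsv"))
    sj <- file.path(cfg$outputDir, "run_summary.json")
    jsonlite::write_json(summary, sj, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files["summary"] <- sj
    res$files <- files
  }
  res
}

# Conservation funnel over simple edges: every edge lands in exactly one
# bucket. Degenerate (all eligible datasets constant) folds into ineligible.
funnelCounts <- function(edgeAssoc) {
  status <- edgeAssoc$status
  call <- edgeAssoc$coherency_call
  list(total = nrow(edgeAssoc),
       ineligible = sum(status %in% c("ineligible", "degenerate")),
       heterogeneous = sum(status == "heterogeneous"),
       coherent = sum(status == "ok" & call == "coherent"),
       incoherent = sum(status == "ok" & call == "incoherent"),
       non_significant = sum(status == "ok" & call == "non_significant"))
}

# Attach per-pair correlation categories to census assignments via the
# ordered direct edge (dual rows use their geneI -> geneII edge).
joinCensusCategories <- function(census, edgeAssoc) {
  key <- paste(edgeAssoc$geneI, edgeAssoc$geneII, sep = "\r")
  ix <- match(paste(census$geneI, census$geneII, sep = "\r"), key)
  census$category <- edgeAssoc$category[ix]
  census$coherency_call <- ifelse(census$class %in% c("Act", "Inh"),
                                  edgeAssoc$coherency_call[ix],
                                  NA_character_)
  census
}
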