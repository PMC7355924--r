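#' Correlate one paired-observation vector pair
#'
#' Computes the chosen correlation coefficient and its two-sided p-value:
#' Pearson through the exact t transform (t = r * sqrt(n-2) / sqrt(1-r^2),
#' n-2 df), Spearman on ranks, Kendall as tie-corrected tau-b. Constant
#' vectors make the correlation undefined; such calls return `r = NA` with a
#' `reason`, and the affected dataset is excluded upstream with a logged
#' reason rather than erroring the whole pair.
#'
#' @param pv paired vectors as returned by [pairObservations()] (list with
#'   `x`, `y`, `n`, `dataset`).
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return list with `dataset`, `method`, `r`, `p`, `n`, `reason`
#'   (NA when defined).
#' @export
correlatePair <- function(pv, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (pv$n < 3L)
    stop("correlation needs more than two paired samples (n = ", pv$n, ")")
  res <- list(dataset = pv$dataset, method = method,
              r = NA_real_, p = NA_real_, n = pv$n, reason = NA_character_)
  if (stats::sd(pv$x) == 0 || stats::sd(pv$y) == 0) {
    res$reason <- "constant_vector"
    return(res)
  }
  ct <- suppressWarnings(
    stats::cor.test(pv$x, pv$y, method = method, alternative = "two.sided",
                    exact = FALSE))
  res$r <- unname(ct$estimate)
  res$p <- ct$p.value
  res
}

#' Assess one gene pair across all eligible datasets
#'
#' Runs the per-dataset correlations, applies the homogeneity rule (all
#' defined nonzero coefficients must share one sign; r = 0 is sign-neutral),
#' and aggregates to a single pair-level coefficient and p-value:
#' \describe{
#'   \item{`aggregate = "weighted"` (default)}{combined r is the
#'     sample-size-weighted mean of the per-dataset coefficients; combined p
#'     is Fisher's combination of the per-dataset two-sided p-values
#'     (a single dataset keeps its own p).}
#'   \item{`aggregate = "max_n"`}{the dataset with the largest n speaks for
#'     the pair.}
#' }
#' Aggregation is only meaningful for homogeneous pairs; heterogeneous pairs
#' are flagged and filtered out of downstream classification.
#'
#' @param geneI,geneII gene identifiers.
#' @param coll an [ExpressionCollection-class].
#' @param method correlation method, see [correlatePair()].
#' @param minN per-dataset eligibility threshold (>= 3).
#' @param aggregate `"weighted"` or `"max_n"`.
#' @return list with `geneI`, `geneII`, `perDataset` (list of correlation
#'   results), `nDatasets` (with defined correlations), `homogeneous`,
#'   `combinedR`, `combinedP`, `status`
#'   (ok / ineligible / degenerate / heterogeneous).
#' @export
assessPair <- function(geneI, geneII, coll,
                       method = c("pearson", "spearman", "kendall"),
                       minN = 3L, aggregate = c("weighted", "max_n")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  pvs <- eligibleDatasets(geneI, geneII, coll, minN)
  out <- list(geneI = geneI, geneII = geneII, perDataset = list(),
              nDatasets = 0L, homogeneous = NA, combinedR = NA_real_,
              combinedP = NA_real_, status = "ineligible")
  if (!length(pvs)) return(out)
  res <- lapply(pvs, correlatePair, method = method)
  out$perDataset <- res
  defined <- res[vapply(res, function(z) is.na(z$reason), logical(1))]
  if (!length(defined)) {
    out$status <- "degenerate"
    return(out)
  }
  r <- vapply(defined, `[[`, numeric(1), "r")
  p <- vapply(defined, `[[`, numeric(1), "p")
  n <- vapply(defined, `[[`, numeric(1), "n")
  out$nDatasets <- length(defined)
  signs <- sign(r)
  out$homogeneous <- length(unique(signs[signs != 0])) <= 1L
  if (!out$homogeneous) {
    out$status <- "heterogeneous"
    return(out)
  }
  if (aggregate == "max_n") {
    k <- which.max(n)
    out$combinedR <- r[k]
    out$combinedP <- p[k]
  } else {
    out$combinedR <- sum(n * r) / sum(n)
    out$combinedP <- if (length(p) == 1L) p else fisherCombine(p)
  }
  out$status <- "ok"
  out
}

# Fisher's method on two-sided p-values: X = -2 sum log p ~ chisq(2k).
fisherCombine <- function(p) {
  p <- pmax(p, .Machine$double.xmin)   # guard log(0)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input. Thin validated
#' wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values (q-values), same order.
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify the correlation sign category of pairs
#'
#' `positive` when q < alpha and combined r > 0; `negative` when q < alpha
#' and combined r < 0; otherwise `non_significant` (adjusted p-values at or
#' above alpha leave the coherency status unestablished).
#'
#' @param r combined correlation coefficient(s).
#' @param q FDR-adjusted p-value(s).
#' @param alpha significance cutoff, default 0.05.
#' @return character vector in
#'   `c("positive", "negative", "non_significant")`.
#' @export
classifySignCategory <- function(r, q, alpha = 0.05) {
  out <- rep("non_significant", length(r))
  out[!is.na(q) & !is.na(r) & q < alpha & r > 0] <- "positive"
  out[!is.na(q) & !is.na(r) & q < alpha & r < 0] <- "negative"
  out
}

#' Coherency call for a signed edge from its correlation category
#'
#' An edge is *coherent* when the correlation sign matches the causal sign
#' (activation with positive correlation, inhibition with negative) and
#' *incoherent* when they contradict; non-significant pairs stay
#' non-significant.
#'
#' @param sign edge sign(s), +1 activation / -1 inhibition.
#' @param category output of [classifySignCategory()].
#' @return character vector in
#'   `c("coherent", "incoherent", "non_significant")`.
#' @export
classifyEdgeCoherency <- function(sign, category) {
  stopifnot(all(sign %in% c(-1L, 1L)))
  out <- rep("non_significant", length(category))
  pos <- category == "positive"
  neg <- category == "negative"
  out[(sign > 0 & pos) | (sign < 0 & neg)] <- "coherent"
  out[(sign > 0 & neg) | (sign < 0 & pos)] <- "incoherent"
  out
}

#' Coherency from differential-expression direction labels
#'
#' The truth-table classifier over DEG flags: an activation edge is coherent
#' when source and target move in the same direction (up/up or down/down);
#' an inhibition edge is coherent when they move oppositely. Of the eight
#' (direction, direction, sign) combinations, exactly four are coherent and
#' four incoherent.
#'
#' @param dirI,dirII directions of the source and target gene, `"up"` or
#'   `"down"` (vectorized).
#' @param sign edge sign(s), +1 or -1.
#' @return character vector in `c("coherent", "incoherent")`.
#' @export
classifyDegCoherency <- function(dirI, dirII, sign) {
  if (any(is.na(dirI)) || any(is.na(dirII)))
    stop("both genes must carry a DEG label")
  ok <- c("up", "down")
  if (!all(dirI %in% ok) || !all(dirII %in% ok))
    stop("DEG directions must be 'up' or 'down'")
  stopifnot(all(sign %in% c(-1L, 1L)))
  same <- dirI == dirII
  ifelse((sign > 0) == same, "coherent", "incoherent")
}

#' The full DEG coherency truth table
#'
#' All eight (dirI, dirII, sign) combinations with their calls; handy for
#' inspection and for the exhaustiveness check.
#'
#' @return data.frame with columns `dirI`, `dirII`, `sign`, `call`.
#' @export
degCoherencyTable <- function() {
  g <- expand.grid(dirI = c("up", "down"), dirII = c("up", "down"),
                   sign = c(1L, -1L), stringsAsFactors = FALSE)
  g$call <- classifyDegCoherency(g$dirI, g$dirII, g$sign)
  g
}

#' Assess many gene pairs and classify them in one FDR family
#'
#' Driver used for both network edges and unconnected null pairs: runs
#' [assessPair()] for every row, applies one Benjamini-Hochberg family over
#' all pairs that produced a combined p-value (status `ok`), and classifies
#' the sign category and — when an edge sign is supplied — the coherency
#' call.
#'
#' @param pairs data.frame with columns `geneI`, `geneII` and optionally
#'   `sign` (+1/-1) plus any extra columns (e.g. `replicate`), carried
#'   through.
#' @param coll an [ExpressionCollection-class].
#' @param method,minN,aggregate see [assessPair()].
#' @param alpha significance cutoff on the adjusted p-value.
#' @return data.frame: input columns plus `n_datasets`, `combined_r`,
#'   `combined_p`, `q`, `homogeneous`, `status`, `category` and (if `sign`
#'   present) `coherency_call`.
#' @export
associatePairs <- function(pairs, coll,
                           method = c("pearson", "spearman", "kendall"),
                           minN = 3L, alpha = 0.05,
                           aggregate = c("weighted", "max_n")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("geneI", "geneII") %in% names(pairs)))
  n <- nrow(pairs)
  res <- vector("list", n)
  for (i in seq_len(n))
    res[[i]] <- assessPair(pairs$geneI[i], pairs$geneII[i], coll,
                           method = method, minN = minN,
                           aggregate = aggregate)
  out <- pairs
  out$n_datasets <- vapply(res, `[[`, integer(1), "nDatasets")
  out$combined_r <- vapply(res, `[[`, numeric(1), "combinedR")
  out$combined_p <- vapply(res, `[[`, numeric(1), "combinedP")
  out$homogeneous <- vapply(res, `[[`, logical(1), "homogeneous")
  out$status <- vapply(res, `[[`, character(1), "status")
  out$q <- NA_real_
  ok <- out$status == "ok"
  if (any(ok)) out$q[ok] <- fdrAdjust(out$combined_p[ok])
  out$category <- rep(NA_character_, n)
  out$category[ok] <- classifySignCategory(out$combined_r[ok], out$q[ok],
                                           alpha)
  if ("sign" %in% names(pairs)) {
    out$coherency_call <- rep(NA_character_, n)
    out$coherency_call[ok] <- classifyEdgeCoherency(out$sign[ok],
                                                    out$category[ok])
  }
  out
}

#' Assess all simple edges of a network
#'
#' Convenience wrapper around [associatePairs()] for the network's edge
#' table (ambiguous-sign pairs are already excluded from that table under
#' the default merge policy).
#'
#' @param net a [SignedNetwork-class].
#' @param coll an [ExpressionCollection-class].
#' @param ... passed to [associatePairs()].
#' @return per-edge association data.frame, see [associatePairs()].
#' @export
associateEdges <- function(net, coll, ...) {
  e <- edgeTable(net)
  pairs <- data.frame(geneI = e$source, geneII = e$target, sign = e$sign,
                      stringsAsFactors = FALSE)
  associatePairs(pairs, coll, ...)
}
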