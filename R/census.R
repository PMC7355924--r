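#' Signed and unsigned adjacency-matrix powers
#'
#' `signedPower(S, k)[i, j]` sums, over all directed walks from i to j of
#' length exactly k, the product of the edge signs along the walk.
#' `unsignedPower(B, k)[i, j]` is the number of such walks. Walks may revisit
#' nodes: the census is defined through matrix self-multiplication, which
#' counts walks, not simple paths.
#'
#' @param S signed adjacency matrix (entries -1/0/+1), see
#'   [signedAdjacency()].
#' @param B unsigned adjacency matrix (entries 0/1), see
#'   [unsignedAdjacency()].
#' @param k walk length, integer >= 1.
#' @return matrix (sparse) of walk sign-sums / walk counts.
#' @export
signedPower <- function(S, k) {
  stopifnot(k >= 1)
  P <- S
  for (i in seq_len(k - 1)) P <- P %*% S
  P
}

#' @rdname signedPower
#' @export
unsignedPower <- function(B, k) {
  stopifnot(k >= 1)
  P <- B
  for (i in seq_len(k - 1)) P <- P %*% B
  P
}

#' Directed reachability within a walk-length horizon
#'
#' `reachability(B, L)[i, j]` is TRUE iff some directed walk i -> j of length
#' between 1 and L exists. With L at least the network diameter this equals
#' the transitive closure, which is why unconnected-pair sampling powers the
#' matrix beyond the diameter.
#'
#' @param B unsigned adjacency (0/1) matrix.
#' @param horizon maximum walk length L >= 1.
#' @return dense logical matrix, same dimnames as `B`.
#' @export
reachability <- function(B, horizon) {
  if (horizon < 1) stop("horizon must be >= 1")
  B <- as.matrix(B) != 0
  acc <- B
  P <- B
  for (k in seq_len(horizon - 1)) {
    P <- (P %*% B) > 0
    new <- P & !acc
    if (!any(new) ) break    # closure reached early
    acc <- acc | P
  }
  acc
}

#' Class map for multi-edge feedback / feed-forward motifs
#'
#' Maps the (direct sign, indirect sign) combination to the motif label, for
#' the feedback context (indirect return walk target -> source) and the
#' feed-forward context (indirect parallel walk source -> target). Negative
#' loops (leg-sign product -1) are the "MN" classes; feed-forward pairs with
#' agreeing legs are the coherent "MFFL" classes. The map is data, not code,
#' so an alternative labeling convention can be swapped in via the
#' `classMap` argument of [censusMulti()].
#'
#' @return data.frame with columns `context`, `sd`, `sp`, `label`.
#' @export
motifClassMap <- function() {
  data.frame(
    context = rep(c("feedback", "feedforward"), each = 4),
    sd = c( 1,  1, -1, -1,   1, -1,  1, -1),
    sp = c( 1, -1, -1,  1,   1, -1, -1,  1),
    label = c("MPFBL1", "MNFBL1", "MPFBL2", "MNFBL2",
              "MFFL1", "MFFL2", "MNFFL1", "MNFFL2"),
    stringsAsFactors = FALSE)
}

#' Census of two-node (dual) feedback loops
#'
#' Unordered gene pairs connected by direct edges in both orientations:
#' both activating -> DPFBL1, both inhibiting -> DPFBL2, mixed signs ->
#' DNFBL (the negative two-node loop). Detected directly from the edge
#' table; equivalent to reading the upper and lower adjacency triangles.
#'
#' @param net a [SignedNetwork-class].
#' @return data.frame with columns `geneI`, `geneII` (geneI < geneII),
#'   `class`, `s_d` (sign of geneI -> geneII), `s_p` (sign of
#'   geneII -> geneI, as character), `k_star` (NA for duals).
#' @export
censusDual <- function(net) {
  e <- edgeTable(net)
  empty <- data.frame(geneI = character(), geneII = character(),
                      class = character(), s_d = integer(),
                      s_p = character(), k_star = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(e)) return(empty)
  fwd <- paste(e$source, e$target, sep = "\r")
  rev <- paste(e$target, e$source, sep = "\r")
  has <- fwd %in% rev
  keep <- has & e$source < e$target   # report each unordered pair once
  if (!any(keep)) return(empty)
  ef <- e[keep, , drop = FALSE]
  back <- e$sign[match(paste(ef$target, ef$source, sep = "\r"), fwd)]
  cls <- ifelse(ef$sign == 1 & back == 1, "DPFBL1",
         ifelse(ef$sign == -1 & back == -1, "DPFBL2", "DNFBL"))
  data.frame(geneI = ef$source, geneII = ef$target, class = cls,
             s_d = ef$sign, s_p = as.character(back),
             k_star = NA_integer_, stringsAsFactors = FALSE)
}

#' Census of multi-edge feedback and feed-forward motifs
#'
#' For every ordered pair (i, j) joined by a direct edge of sign s_d, looks
#' for the shortest *indirect* walk of length k in \[2, radius\]: a return
#' walk j -> i defines a feedback motif, a parallel walk i -> j a
#' feed-forward motif. The indirect sign s_p at that shortest length is read
#' off the signed power: when every length-k* walk carries the same sign
#' (|signed| equals the walk count) s_p is that sign; otherwise the pair is
#' sign-mixed at k* and is excluded from the class (a single net sign is
#' required for a label). The (s_d, s_p) combination is mapped to the class
#' label via `classMap`.
#'
#' The radius of the giant component is the walk-length horizon: the signed
#' and unsigned adjacency matrices are powered up to that magnitude.
#'
#' @param net a [SignedNetwork-class] (typically the giant component).
#' @param radius walk-length horizon; default: radius of the undirected
#'   projection of the giant component, see [networkMetrics()].
#' @param classMap see [motifClassMap()].
#' @return data.frame with columns `geneI`, `geneII` (the ordered direct
#'   edge), `context`, `class`, `s_d`, `s_p` (character; `"mixed"` rows are
#'   excluded), `k_star`. Zero rows when the horizon is below 2.
#' @export
censusMulti <- function(net, radius = NULL, classMap = motifClassMap()) {
  if (is.null(radius)) radius <- networkMetrics(net)$radius
  e <- edgeTable(net)
  empty <- data.frame(geneI = character(), geneII = character(),
                      context = character(), class = character(),
                      s_d = integer(), s_p = character(),
                      k_star = integer(), stringsAsFactors = FALSE)
  if (!nrow(e) || radius < 2) return(empty)
  S <- signedAdjacency(net)
  B <- unsignedAdjacency(net)
  ii <- match(e$source, geneIds(net))
  jj <- match(e$target, geneIds(net))
  res <- list()
  for (context in c("feedback", "feedforward")) {
    idx <- if (context == "feedback") cbind(jj, ii) else cbind(ii, jj)
    kStar <- rep(NA_integer_, nrow(e))
    wSign <- rep(NA_real_, nrow(e))
    wCount <- rep(NA_real_, nrow(e))
    Sk <- S
    Bk <- B
    for (k in 2:radius) {
      Sk <- Sk %*% S
      Bk <- Bk %*% B
      hit <- is.na(kStar) & Bk[idx] > 0
      if (any(hit)) {
        kStar[hit] <- k
        wSign[hit] <- Sk[idx][hit]
        wCount[hit] <- Bk[idx][hit]
      }
      if (!anyNA(kStar)) break
    }
    found <- !is.na(kStar)
    if (!any(found)) next
    sp <- ifelse(abs(wSign[found]) == wCount[found],
                 as.character(sign(wSign[found])), "mixed")
    df <- data.frame(geneI = e$source[found], geneII = e$target[found],
                     context = context, class = NA_character_,
                     s_d = e$sign[found], s_p = sp,
                     k_star = kStar[found], stringsAsFactors = FALSE)
    pure <- df$s_p != "mixed"
    df <- df[pure, , drop = FALSE]
    if (!nrow(df)) next
    cm <- classMap[classMap$context == context, ]
    key <- paste(df$s_d, df$s_p)
    df$class <- cm$label[match(key, paste(cm$sd, cm$sp))]
    res[[context]] <- df
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full subgraph census
#'
#' One table of class assignments over the whole Table-1-style vocabulary:
#' the simple classes Act and Inh (every direct edge, by its own sign), the
#' dual two-node loops, and the multi-edge feedback/feed-forward classes.
#' Classes are deliberately not mutually exclusive — an edge inside a dual
#' loop is still counted under Act or Inh, matching the overlapping tallies
#' of a motif census.
#'
#' @param net a [SignedNetwork-class].
#' @param radius horizon for [censusMulti()]; default from
#'   [networkMetrics()].
#' @param classMap see [motifClassMap()].
#' @return data.frame with columns `geneI`, `geneII`, `class`, `s_d`, `s_p`,
#'   `k_star`.
#' @export
censusAll <- function(net, radius = NULL, classMap = motifClassMap()) {
  e <- edgeTable(net)
  simple <- data.frame(geneI = e$source, geneII = e$target,
                       class = ifelse(e$sign > 0, "Act", "Inh"),
                       s_d = e$sign, s_p = NA_character_,
                       k_star = NA_integer_, stringsAsFactors = FALSE)
  dual <- censusDual(net)
  multi <- censusMulti(net, radius = radius, classMap = classMap)
  multi <- multi[, c("geneI", "geneII", "class", "s_d", "s_p", "k_star")]
  out <- rbind(simple, dual, multi)
  rownames(out) <- NULL
  out
}

#' Sample unconnected gene pairs (the null class)
#'
#' Draws R replicate sets of m distinct unordered gene pairs that have no
#' directed walk between them in either orientation (no immediate or
#' non-immediate interaction), and that are expression-eligible so the same
#' downstream correlation analysis can be applied to every sampled pair.
#' Pairs whose sign was ambiguous at merge time are also excluded: they are
#' connected, just unsigned.
#'
#' The adjacency matrix is self-multiplied beyond the network diameter; the
#' default horizon is n - 1, i.e. the full directed transitive closure
#' (directed path lengths can exceed the *undirected* diameter, and
#' [reachability()] stops as soon as the closure is reached, so this costs
#' no extra multiplications).
#'
#' Replicate seeds are derived deterministically from the master seed, so a
#' fixed seed reproduces the sets bit-for-bit.
#'
#' @param net a [SignedNetwork-class] (typically the giant component).
#' @param coll an [ExpressionCollection-class].
#' @param m pairs per replicate (the study design uses 1000).
#' @param R number of replicates (the study design uses 10).
#' @param seed master RNG seed, integer.
#' @param minN eligibility threshold, see [eligibleDatasets()].
#' @param horizon walk-length horizon; default n - 1 (transitive closure,
#'   which is always beyond the diameter).
#' @return data.frame with columns `replicate`, `geneI`, `geneII`.
#' @export
sampleUGP <- function(net, coll, m = 1000L, R = 10L, seed = 1L,
                      minN = 3L, horizon = NULL) {
  if (is.null(horizon)) horizon <- max(length(geneIds(net)) - 1L, 1L)
  B <- unsignedAdjacency(net)
  reach <- reachability(B, horizon)
  nodes <- geneIds(net)
  unconnected <- !reach & !t(reach)
  unconnected[lower.tri(unconnected, diag = TRUE)] <- FALSE
  amb <- ambiguousPairs(net)
  if (nrow(amb)) {
    ai <- match(pmin(amb$source, amb$target), nodes)
    aj <- match(pmax(amb$source, amb$target), nodes)
    unconnected[cbind(ai, aj)] <- FALSE
  }
  cand <- which(unconnected, arr.ind = TRUE)
  if (!nrow(cand))
    stop("no unconnected gene pairs available (0 < m = ", m, ")")
  gI <- nodes[cand[, 1L]]
  gII <- nodes[cand[, 2L]]
  elig <- eligiblePairMask(gI, gII, coll, minN)
  gI <- gI[elig]; gII <- gII[elig]
  if (length(gI) < m)
    stop("insufficient unconnected eligible pairs: ", length(gI),
         " available, ", m, " requested")
  out <- vector("list", R)
  for (r in seq_len(R)) {
    rs <- (as.numeric(seed) + 7919 * r) %% 2147483647
    withSeed(as.integer(rs), {
      pick <- sample.int(length(gI), m)
    })
    out[[r]] <- data.frame(replicate = r, geneI = gI[pick], geneII = gII[pick],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Evaluate expr under a temporary RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
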