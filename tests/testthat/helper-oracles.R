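# Independent brute-force oracles. These deliberately avoid the package's
# matrix-power / igraph code paths: walks are enumerated explicitly and
# shortest paths come from a hand-rolled queue BFS.

# All directed walks of exact length k for k in 1..kmax: returns, per k,
# matrices of walk counts and walk sign-product sums, by explicit frontier
# expansion (every row of a frontier is one walk).
oracleWalks <- function(edges, nodes, kmax) {
  n <- length(nodes)
  res <- lapply(seq_len(kmax), function(k)
    list(count = matrix(0, n, n, dimnames = list(nodes, nodes)),
         sign = matrix(0, n, n, dimnames = list(nodes, nodes))))
  for (s in nodes) {
    frontier <- data.frame(cur = s, prod = 1, stringsAsFactors = FALSE)
    for (k in seq_len(kmax)) {
      if (!nrow(frontier)) break
      step <- merge(frontier, edges, by.x = "cur", by.y = "source")
      if (!nrow(step)) break
      frontier <- data.frame(cur = step$target, prod = step$prod * step$sign,
                             stringsAsFactors = FALSE)
      cnt <- tapply(rep(1, nrow(frontier)), frontier$cur, sum)
      sgn <- tapply(frontier$prod, frontier$cur, sum)
      res[[k]]$count[s, names(cnt)] <- cnt
      res[[k]]$sign[s, names(sgn)] <- sgn
    }
  }
  res
}

# Queue BFS over an adjacency list; returns distances from `start`
# (Inf where unreachable).
oracleBfs <- function(adj, nodes, start) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

adjacencyList <- function(edges, nodes, directed = TRUE) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$source[i]]] <- c(adj[[edges$source[i]]], edges$target[i])
    if (!directed)
      adj[[edges$target[i]]] <- c(adj[[edges$target[i]]], edges$source[i])
  }
  adj
}

# Diameter and radius from all-pairs BFS on the undirected projection,
# restricted to the largest component (ties: component with the smallest
# lexicographic member).
oracleMetrics <- function(edges, nodes) {
  adj <- adjacencyList(edges, nodes, directed = FALSE)
  dl <- lapply(nodes, function(s) oracleBfs(adj, nodes, s))
  names(dl) <- nodes
  comp <- lapply(dl, function(d) sort(names(d)[is.finite(d)]))
  sizes <- lengths(comp)
  giants <- unique(comp[sizes == max(sizes)])
  giant <- giants[[order(vapply(giants, `[`, character(1), 1L))[1L]]]
  ecc <- vapply(giant, function(s) max(dl[[s]][giant]), numeric(1))
  list(giantSize = length(giant), diameter = as.integer(max(ecc)),
       radius = as.integer(min(ecc)))
}

# TRUE iff a directed path start -> goal exists (unbounded BFS).
oracleReachable <- function(edges, nodes, start, goal) {
  adj <- adjacencyList(edges, nodes, directed = TRUE)
  unname(is.finite(oracleBfs(adj, nodes, start)[goal]))
}

# Brute-force motif classifier for one ordered direct edge (i, j): finds the
# shortest indirect walk (return walk j -> i for feedback, parallel walk
# i -> j for feed-forward) of length 2..radius via enumerated walks, demands
# sign unanimity at that length, and maps (s_d, s_p) to the label with
# explicit if-rules (independent of motifClassMap()).
oracleClassify <- function(walks, i, j, sd, radius, context) {
  for (k in 2:radius) {
    if (k > length(walks)) break
    cnt <- if (context == "feedback") walks[[k]]$count[j, i]
           else walks[[k]]$count[i, j]
    if (cnt > 0) {
      sgn <- if (context == "feedback") walks[[k]]$sign[j, i]
             else walks[[k]]$sign[i, j]
      if (abs(sgn) != cnt) return(list(class = NA_character_, k = k))
      sp <- sign(sgn)
      label <-
        if (context == "feedback") {
          if (sd == 1 && sp == 1) "MPFBL1"
          else if (sd == 1 && sp == -1) "MNFBL1"
          else if (sd == -1 && sp == -1) "MPFBL2"
          else "MNFBL2"
        } else {
          if (sd == 1 && sp == 1) "MFFL1"
          else if (sd == -1 && sp == -1) "MFFL2"
          else if (sd == 1 && sp == -1) "MNFFL1"
          else "MNFFL2"
        }
      return(list(class = label, k = k))
    }
  }
  list(class = NULL, k = NA_integer_)
}

# Random signed directed graph as an edge-list data.frame (no self-loops,
# unique ordered pairs).
randomSignedEdges <- function(nNodes, nEdges, pAct = 0.6) {
  nodes <- sprintf("n%02d", seq_len(nNodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- pairs[sample.int(nrow(pairs), min(nEdges, nrow(pairs))), ]
  pick$sign <- ifelse(stats::runif(nrow(pick)) < pAct, 1L, -1L)
  rownames(pick) <- NULL
  pick
}

edgesToNetwork <- function(edges) {
  mergeEdgeLists(list(edges), conflictPolicy = "ambiguous")
}

# Tiny expression collection built in code: given genes, returns `nDatasets`
# matrices of independent N(0,1) with `nSamples` columns each.
nullCollection <- function(genes, nDatasets = 2, nSamples = 10, seed = 1) {
  ds <- list()
  for (d in seq_len(nDatasets)) {
    set.seed(seed + d)
    m <- matrix(rnorm(length(genes) * nSamples), nrow = length(genes),
                dimnames = list(genes, paste0("s", seq_len(nSamples))))
    ds[[paste0("ds", d)]] <- m
  }
  ExpressionCollection(ds)
}

writeTempEdgeList <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}
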