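#' Simulation configuration with planted coherency
#'
#' Defines the generative study conditions used throughout the package's
#' validation: a random signed directed network with injected two-node loops
#' and triangles (so every motif class is populated), several independent
#' expression datasets in which a planted fraction of edges drives the
#' target linearly from the source, and optional per-dataset gene
#' missingness.
#'
#' Defaults mirror the validation design: 200 random edges over 150 genes,
#' activation probability 0.72 (the activation share typical of curated
#' signaling edge lists), five independent datasets of 20 samples each,
#' planted coherent fraction 0.8 with effect size beta = 1 and noise sd
#' sigma = 0.5, and 5% of genes unmeasured per dataset.
#'
#' @param nGenes number of genes.
#' @param nEdges number of random directed edges (injected motifs extra).
#' @param pAct probability an edge is an activation (+1).
#' @param nDual injected two-node loops, cycling through the sign
#'   combinations (+,+), (-,-), (+,-).
#' @param nTriangles injected three-node motifs, cycling through all eight
#'   feedback / feed-forward (direct, indirect) sign combinations.
#' @param nDatasets number of independent expression datasets.
#' @param sampleRange integer range (min, max) of samples per dataset.
#' @param phi planted coherent fraction of edges, in \[0, 1\].
#' @param incoherencyMode `"anti_sign"` (incoherent edges drive the target
#'   with the flipped sign — sharp recovery) or `"independent"` (incoherent
#'   edges exert no effect, so they behave like null pairs).
#' @param beta linear effect size (> 0).
#' @param sigma noise standard deviation (>= 0).
#' @param missingness per-dataset probability a gene is unmeasured.
#' @param seed master RNG seed (integer; sub-seeds are derived from it).
#' @return list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(nGenes = 150L, nEdges = 200L, pAct = 0.72,
                             nDual = 6L, nTriangles = 8L, nDatasets = 5L,
                             sampleRange = c(20L, 20L), phi = 0.8,
                             incoherencyMode = c("anti_sign", "independent"),
                             beta = 1, sigma = 0.5, missingness = 0.05,
                             seed = 1L) {
  incoherencyMode <- match.arg(incoherencyMode)
  stopifnot(nGenes >= 4, nEdges <= as.numeric(nGenes) * (nGenes - 1),
            pAct >= 0, pAct <= 1, phi >= 0, phi <= 1,
            beta > 0, sigma >= 0, missingness >= 0, missingness < 1,
            length(sampleRange) == 2, sampleRange[1] >= 3,
            sampleRange[2] >= sampleRange[1])
  cfg <- list(nGenes = as.integer(nGenes), nEdges = as.integer(nEdges),
              pAct = pAct, nDual = as.integer(nDual),
              nTriangles = as.integer(nTriangles),
              nDatasets = as.integer(nDatasets),
              sampleRange = as.integer(sampleRange), phi = phi,
              incoherencyMode = incoherencyMode, beta = beta, sigma = sigma,
              missingness = missingness, seed = as.integer(seed))
  class(cfg) <- "simulationConfig"
  cfg
}

deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Simulate a signed directed network with planted edge coherency
#'
#' Draws `nEdges` distinct directed edges uniformly over ordered non-self
#' gene pairs, signs them +1 with probability `pAct`, then injects `nDual`
#' two-node loops and `nTriangles` three-node feedback/feed-forward motifs
#' (on freshly sampled pairs/triples, replacing any clashing random edge) so
#' the full motif vocabulary is populated. Each edge is independently
#' planted as `coherent` with probability `phi`, else `incoherent`.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `network` (a [SignedNetwork-class]) and `truth`
#'   (data.frame `source`, `target`, `sign`, `label`).
#' @export
simulateNetwork <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  withSeed(deriveSeed(cfg$seed, 0), {
    # random ordered pairs without self-loops, sampled without replacement
    idx <- sample.int(as.numeric(cfg$nGenes) * (cfg$nGenes - 1), cfg$nEdges)
    src0 <- (idx - 1) %/% (cfg$nGenes - 1) + 1
    off <- (idx - 1) %% (cfg$nGenes - 1) + 1
    tgt0 <- ifelse(off >= src0, off + 1, off)
    sgn <- ifelse(stats::runif(cfg$nEdges) < cfg$pAct, 1L, -1L)
    el <- data.frame(source = genes[src0], target = genes[tgt0], sign = sgn,
                     stringsAsFactors = FALSE)

    dualSigns <- list(c(1L, 1L), c(-1L, -1L), c(1L, -1L))
    for (i in seq_len(cfg$nDual)) {
      pr <- sample(genes, 2L)
      ss <- dualSigns[[(i - 1L) %% 3L + 1L]]
      el <- rbind(el,
                  data.frame(source = pr[1], target = pr[2], sign = ss[1]),
                  data.frame(source = pr[2], target = pr[1], sign = ss[2]))
    }
    # (context, s_d, s_p) combinations; legs (a, b) chosen with a*b = s_p
    triPatterns <- list(
      list("fb",  1L,  1L), list("fb",  1L, -1L),
      list("fb", -1L, -1L), list("fb", -1L,  1L),
      list("ff",  1L,  1L), list("ff", -1L, -1L),
      list("ff",  1L, -1L), list("ff", -1L,  1L))
    for (i in seq_len(cfg$nTriangles)) {
      tp <- triPatterns[[(i - 1L) %% 8L + 1L]]
      tr <- sample(genes, 3L)
      a <- 1L
      b <- tp[[3L]]   # leg product a*b equals the requested indirect sign
      legs <- if (tp[[1L]] == "fb")
        data.frame(source = c(tr[1], tr[2], tr[3]),
                   target = c(tr[2], tr[3], tr[1]),
                   sign = c(tp[[2L]], a, b))
      else
        data.frame(source = c(tr[1], tr[1], tr[3]),
                   target = c(tr[2], tr[3], tr[2]),
                   sign = c(tp[[2L]], a, b))
      el <- rbind(el, legs)
    }
    # later (injected) rows win on ordered-pair clashes
    key <- paste(el$source, el$target, sep = "\r")
    el <- el[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    el <- el[el$source != el$target, , drop = FALSE]
    rownames(el) <- NULL
    label <- ifelse(stats::runif(nrow(el)) < cfg$phi, "coherent",
                    "incoherent")
  })
  el$provenance <- "synthetic"
  net <- mergeEdgeLists(list(el), conflictPolicy = "ambiguous")
  truth <- data.frame(source = el$source, target = el$target, sign = el$sign,
                      label = label, stringsAsFactors = FALSE)
  list(network = net, truth = truth)
}

#' Simulate multi-dataset expression with planted linear effects
#'
#' Per dataset: every gene starts as an independent standard normal across
#' samples; each target of at least one effect-carrying edge is then
#' overwritten by the sum of its parents' contributions
#' `s_eff * beta * x_parent` plus Gaussian noise of sd `sigma`, where
#' `s_eff` is the edge sign for planted-coherent edges and the flipped sign
#' for incoherent edges under `anti_sign` (under `independent`, incoherent
#' edges contribute nothing). Targets are processed in a Kahn-style
#' dependency order; cycles are broken at the lexicographically smallest
#' remaining gene, whose not-yet-finalized parents enter with their initial
#' values (a single deterministic Gauss-Seidel-style pass). Unconnected
#' genes therefore stay mutually independent — the null class. Finally each
#' gene is dropped from the dataset with probability `missingness`.
#'
#' @param net a [SignedNetwork-class] from [simulateNetwork()].
#' @param truth the planted-truth data.frame from [simulateNetwork()].
#' @param cfg the same [simulationConfig()].
#' @return An [ExpressionCollection-class] with datasets `ds1..dsK`.
#' @export
simulateExpression <- function(net, truth, cfg) {
  genes <- geneIds(net)
  eff <- truth
  eff$s_eff <- ifelse(eff$label == "coherent", eff$sign,
                      if (cfg$incoherencyMode == "anti_sign") -eff$sign
                      else 0L)
  eff <- eff[eff$s_eff != 0, , drop = FALSE]
  ord <- targetOrder(eff, genes)
  parentsOf <- split(seq_len(nrow(eff)), eff$target)
  ds <- list()
  for (d in seq_len(cfg$nDatasets)) {
    id <- paste0("ds", d)
    withSeed(deriveSeed(cfg$seed, 1000 + d), {
      nS <- if (cfg$sampleRange[1] == cfg$sampleRange[2]) cfg$sampleRange[1]
            else sample(cfg$sampleRange[1]:cfg$sampleRange[2], 1L)
      X <- matrix(stats::rnorm(length(genes) * nS), nrow = length(genes),
                  dimnames = list(genes, paste0(id, "_s", seq_len(nS))))
      E <- cfg$sigma * matrix(stats::rnorm(length(genes) * nS),
                              nrow = length(genes))
      for (g in ord) {
        pe <- eff[parentsOf[[g]], , drop = FALSE]
        contrib <- colSums(pe$s_eff * cfg$beta *
                             X[pe$source, , drop = FALSE])
        X[g, ] <- contrib + E[match(g, genes), ]
      }
      keep <- stats::runif(length(genes)) >= cfg$missingness
    })
    if (sum(keep) < 2L) keep[1:2] <- TRUE
    ds[[id]] <- X[keep, , drop = FALSE]
  }
  ExpressionCollection(ds,
    manifest = data.frame(id = names(ds), tags = "synthetic",
                          stringsAsFactors = FALSE))
}

# Kahn-style ordering of effect targets; cycles broken at the smallest
# remaining gene (deterministic).
targetOrder <- function(eff, genes) {
  pending <- sort(unique(eff$target))
  ord <- character()
  while (length(pending)) {
    blockers <- vapply(pending, function(g) {
      p <- eff$source[eff$target == g]
      any(p %in% pending & p != g)
    }, logical(1))
    ready <- pending[!blockers]
    if (!length(ready)) ready <- pending[1L]   # cycle: break at smallest
    ord <- c(ord, ready)
    pending <- setdiff(pending, ready)
  }
  ord
}

#' Simulate differential-expression labels consistent with planted coherency
#'
#' Walks the edges in order: an unlabeled source gets a random up/down
#' label; an unlabeled target is then labeled so the edge realizes its
#' planted status under the truth-table rule (coherent activation: same
#' direction; coherent inhibition: opposite; incoherent: the flip; under
#' `independent` mode incoherent targets are labeled at random). Genes that
#' are already labeled keep their first label, and untouched genes are
#' labeled at random, so the planted fraction is recoverable up to
#' collisions at shared targets.
#'
#' @param net a [SignedNetwork-class].
#' @param truth planted truth from [simulateNetwork()].
#' @param cfg the [simulationConfig()].
#' @return Named character vector gene -> `"up"`/`"down"`.
#' @export
simulateDegLabels <- function(net, truth, cfg) {
  genes <- geneIds(net)
  lab <- stats::setNames(rep(NA_character_, length(genes)), genes)
  withSeed(deriveSeed(cfg$seed, 2000), {
    for (i in seq_len(nrow(truth))) {
      s <- truth$source[i]; t <- truth$target[i]
      if (is.na(lab[s])) lab[s] <- sample(c("up", "down"), 1L)
      if (is.na(lab[t])) {
        coherentDir <- if (truth$sign[i] > 0) lab[s]
                       else setdiff(c("up", "down"), lab[s])
        lab[t] <- if (truth$label[i] == "coherent") coherentDir
                  else if (cfg$incoherencyMode == "independent")
                    sample(c("up", "down"), 1L)
                  else setdiff(c("up", "down"), coherentDir)
      }
    }
    miss <- is.na(lab)
    lab[miss] <- sample(c("up", "down"), sum(miss), replace = TRUE)
  })
  lab
}

#' Generate a complete synthetic study
#'
#' Runs [simulateNetwork()], [simulateExpression()] and
#' [simulateDegLabels()] under one configuration and optionally writes the
#' standard file bundle: `edges.tsv` (3-column signed edge list),
#' `ds<k>.tsv` expression matrices, `manifest.yaml`, `deg_labels.tsv` and
#' `planted_truth.tsv`. All outputs are bit-reproducible from `cfg$seed`.
#'
#' @param cfg a [simulationConfig()].
#' @param dir optional output directory (created if needed).
#' @return list with `network`, `truth`, `expression`, `degLabels`,
#'   and `files` (named paths, when `dir` is given).
#' @export
simulateStudy <- function(cfg = simulationConfig(), dir = NULL) {
  sim <- simulateNetwork(cfg)
  coll <- simulateExpression(sim$network, sim$truth, cfg)
  deg <- simulateDegLabels(sim$network, sim$truth, cfg)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(edges = file.path(dir, "edges.tsv"),
               manifest = file.path(dir, "manifest.yaml"),
               deg = file.path(dir, "deg_labels.tsv"),
               truth = file.path(dir, "planted_truth.tsv"))
    writeEdgeList(sim$network, files[["edges"]])
    entries <- list()
    for (id in datasetIds(coll)) {
      p <- file.path(dir, paste0(id, ".tsv"))
      m <- exprsMatrix(coll@datasets[[id]])
      utils::write.table(
        data.frame(gene = rownames(m), m, check.names = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      entries[[id]] <- list(id = id, path = basename(p), tags = "synthetic")
      files[[paste0("expr_", id)]] <- p
    }
    yaml::write_yaml(unname(entries), files[["manifest"]])
    utils::write.table(
      data.frame(gene = names(deg), direction = unname(deg)),
      files[["deg"]], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, files[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(network = sim$network, truth = sim$truth, expression = coll,
       degLabels = deg, files = files)
}
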