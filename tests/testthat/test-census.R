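test_that("matrix powers sum walk sign-products and counts", {
  chain <- edgesToNetwork(data.frame(source = c("A", "B"),
                                     target = c("B", "C"),
                                     sign = c(1L, -1L)))
  S <- signedAdjacency(chain)
  B <- unsignedAdjacency(chain)
  expect_equal(as.numeric(signedPower(S, 2)["A", "C"]), -1)
  expect_equal(as.numeric(unsignedPower(B, 2)["A", "C"]), 1)

  tri <- edgesToNetwork(data.frame(source = c("A", "B", "C"),
                                   target = c("B", "C", "A"),
                                   sign = c(1L, 1L, -1L)))
  expect_equal(as.numeric(signedPower(signedAdjacency(tri), 3)["A", "A"]), -1)
})

test_that("matrix powers equal explicit walk enumeration on random graphs", {
  set.seed(21)
  for (rep in 1:10) {
    edges <- randomSignedEdges(sample(5:10, 1), sample(8:20, 1))
    net <- edgesToNetwork(edges)
    S <- as.matrix(signedAdjacency(net))
    B <- as.matrix(unsignedAdjacency(net))
    walks <- oracleWalks(edgeTable(net), geneIds(net), 5)
    for (k in 1:5) {
      expect_equal(as.matrix(signedPower(S, k)), walks[[k]]$sign,
                   ignore_attr = TRUE)
      expect_equal(as.matrix(unsignedPower(B, k)), walks[[k]]$count,
                   ignore_attr = TRUE)
    }
  }
})

test_that("reachability matches BFS within and beyond the horizon", {
  chain <- edgesToNetwork(data.frame(source = c("A", "B"),
                                     target = c("B", "C"), sign = 1L))
  R2 <- reachability(unsignedAdjacency(chain), 2)
  expect_true(R2["A", "C"])
  expect_false(R2["C", "A"])

  two <- edgesToNetwork(data.frame(source = c("A", "C"),
                                   target = c("B", "D"), sign = 1L))
  Rt <- reachability(unsignedAdjacency(two), 3)
  expect_false(any(Rt[c("A", "B"), c("C", "D")]))

  expect_error(reachability(unsignedAdjacency(chain), 0), "horizon")

  set.seed(22)
  for (rep in 1:8) {
    edges <- randomSignedEdges(sample(6:20, 1), sample(10:30, 1))
    net <- edgesToNetwork(edges)
    nodes <- geneIds(net)
    Rm <- reachability(unsignedAdjacency(net), length(nodes) - 1)
    for (i in nodes[1:3]) for (j in nodes[1:3]) {
      if (i == j) next
      expect_identical(unname(Rm[i, j]),
                       oracleReachable(edgeTable(net), nodes, i, j))
    }
  }
})

test_that("dual loops classify by their two direct signs", {
  mk <- function(s1, s2) edgesToNetwork(
    data.frame(source = c("A", "B"), target = c("B", "A"),
               sign = c(s1, s2)))
  expect_equal(censusDual(mk(1L, -1L))$class, "DNFBL")
  expect_equal(censusDual(mk(1L, 1L))$class, "DPFBL1")
  expect_equal(censusDual(mk(-1L, -1L))$class, "DPFBL2")
  d <- censusDual(mk(1L, -1L))
  expect_equal(d$geneI, "A")    # unordered pair reported once
  expect_true(is.na(d$k_star))
  # a network without mutual edges has no dual loops
  expect_equal(nrow(censusDual(edgesToNetwork(
    data.frame(source = "A", target = "B", sign = 1L)))), 0L)
})

test_that("multi-edge classes follow the (direct, indirect) sign map", {
  fb <- edgesToNetwork(data.frame(source = c("A", "B", "C"),
                                  target = c("B", "C", "A"),
                                  sign = c(1L, 1L, 1L)))
  res <- censusMulti(fb, radius = 2)
  ab <- res[res$geneI == "A" & res$geneII == "B" & res$context == "feedback", ]
  expect_equal(ab$class, "MPFBL1")
  expect_equal(ab$k_star, 2L)

  ff <- edgesToNetwork(data.frame(source = c("A", "A", "C"),
                                  target = c("B", "C", "B"),
                                  sign = c(1L, 1L, -1L)))
  res <- censusMulti(ff, radius = 2)
  ab <- res[res$geneI == "A" & res$geneII == "B", ]
  expect_equal(ab$context, "feedforward")
  expect_equal(ab$class, "MNFFL1")
})

test_that("census agrees with the brute-force walk-enumeration classifier", {
  set.seed(23)
  for (rep in 1:12) {
    edges <- randomSignedEdges(sample(6:15, 1), sample(10:40, 1))
    net <- edgesToNetwork(edges)
    radius <- 4
    got <- censusMulti(net, radius = radius)
    walks <- oracleWalks(edgeTable(net), geneIds(net), radius)
    e <- edgeTable(net)
    for (i in seq_len(nrow(e))) {
      for (context in c("feedback", "feedforward")) {
        want <- oracleClassify(walks, e$source[i], e$target[i], e$sign[i],
                               radius, context)
        gi <- got[got$geneI == e$source[i] & got$geneII == e$target[i] &
                    got$context == context, ]
        if (is.null(want$class)) {
          expect_equal(nrow(gi), 0L)        # no indirect walk within horizon
        } else if (is.na(want$class)) {
          expect_equal(nrow(gi), 0L)        # sign-mixed at k*: excluded
        } else {
          expect_equal(gi$class, want$class)
          expect_equal(gi$k_star, want$k)
        }
      }
    }
  }
})

test_that("multi census at k* = 1 on the reverse edge reproduces dual classes", {
  # a pure two-node loop: the return walk of length 2 passes through the
  # forward edge, so signs at k = 2 mirror the dual logic
  net <- edgesToNetwork(data.frame(source = c("A", "B"), target = c("B", "A"),
                                   sign = c(1L, -1L)))
  dual <- censusDual(net)
  expect_equal(dual$class, "DNFBL")
  # every dual edge is also counted under Act/Inh in the full census
  census <- censusAll(net, radius = 2)
  expect_setequal(census$class[census$class %in% c("Act", "Inh")],
                  c("Act", "Inh"))
  expect_true("DNFBL" %in% census$class)
})

test_that("UGP sampling excludes all connected pairs and reproduces by seed", {
  el <- data.frame(source = c("A", "C"), target = c("B", "D"), sign = 1L)
  net <- mergeEdgeLists(list(el))
  genes <- geneIds(net)
  coll <- nullCollection(genes, nDatasets = 1, nSamples = 6, seed = 9)
  u <- sampleUGP(net, coll, m = 4, R = 2, seed = 5)
  expect_equal(nrow(u), 8L)
  got <- unique(paste(u$geneI, u$geneII))
  expect_setequal(got, c("A C", "A D", "B C", "B D"))

  u2 <- sampleUGP(net, coll, m = 4, R = 2, seed = 5)
  expect_identical(u, u2)
  u3 <- sampleUGP(net, coll, m = 4, R = 2, seed = 6)
  expect_false(identical(u, u3))

  expect_error(sampleUGP(net, coll, m = 5, R = 1, seed = 1),
               "insufficient")

  scc <- mergeEdgeLists(list(data.frame(source = c("A", "B"),
                                        target = c("B", "A"), sign = 1L)))
  expect_error(sampleUGP(scc, nullCollection(c("A", "B")), m = 1, R = 1,
                         seed = 1), "no unconnected|insufficient")
})

test_that("no sampled UGP has a directed path in either direction (BFS)", {
  set.seed(24)
  cfg <- simulationConfig(nGenes = 40, nEdges = 50, nDual = 2,
                          nTriangles = 4, nDatasets = 2,
                          sampleRange = c(8L, 8L), seed = 31)
  st <- simulateStudy(cfg)
  gc <- giantComponent(st$network)
  u <- sampleUGP(gc, st$expression, m = 20, R = 2, seed = 31)
  e <- edgeTable(gc)
  nodes <- geneIds(gc)
  for (i in seq_len(nrow(u))) {
    expect_false(oracleReachable(e, nodes, u$geneI[i], u$geneII[i]))
    expect_false(oracleReachable(e, nodes, u$geneII[i], u$geneI[i]))
  }
})
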