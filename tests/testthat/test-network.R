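test_that("edge lists parse with sign mapping, self-loop and duplicate handling", {
  p <- writeTempEdgeList(c("A\tB\tactivation", "B\tC\tinhibition"))
  el <- readEdgeList(p)
  expect_equal(nrow(el), 2L)
  expect_equal(el$sign, c(1L, -1L))

  p <- writeTempEdgeList(c("A\tA\tactivation"))
  expect_message(el <- readEdgeList(p), "self-loop")
  expect_equal(nrow(el), 0L)
  expect_equal(attr(el, "selfLoops"), 1L)

  p <- writeTempEdgeList(c("A\tB\tactivation", "A\tB\tactivation"))
  el <- readEdgeList(p)
  expect_equal(nrow(el), 1L)
  expect_equal(attr(el, "duplicates"), 1L)

  # optional header, numeric sign tokens, SIF dialect
  p <- writeTempEdgeList(c("source\ttarget\tsign", "A\tB\t1", "B\tC\t-1"))
  expect_equal(readEdgeList(p)$sign, c(1L, -1L))
  p <- writeTempEdgeList(c("A\tactivates\tB", "B\tinhibits\tC"))
  expect_equal(readEdgeList(p, dialect = "sif")$sign, c(1L, -1L))
})

test_that("malformed rows and unknown sign tokens are rejected with context", {
  p <- writeTempEdgeList(c("A\tB\tactivation", "A\tB"))
  expect_error(readEdgeList(p), "line 2")
  p <- writeTempEdgeList(c("A\tB\tmaybe"))
  expect_error(readEdgeList(p), "unknown sign token 'maybe'")
})

test_that("merge policies handle conflicting signs as specified", {
  a <- data.frame(source = "A", target = "B", sign = 1L)
  b <- data.frame(source = "B", target = "C", sign = -1L)
  net <- mergeEdgeLists(list(a, b))
  expect_equal(nrow(edgeTable(net)), 2L)

  conf <- list(data.frame(source = "A", target = "B", sign = 1L),
               data.frame(source = "A", target = "B", sign = -1L))
  amb <- mergeEdgeLists(conf, conflictPolicy = "ambiguous")
  expect_equal(nrow(edgeTable(amb)), 0L)
  expect_equal(ambiguousPairs(amb),
               data.frame(source = "A", target = "B"))
  S <- signedAdjacency(amb)
  expect_equal(sum(S != 0), 0)

  drp <- mergeEdgeLists(conf, conflictPolicy = "drop")
  expect_equal(nrow(edgeTable(drp)), 0L)
  expect_equal(nrow(ambiguousPairs(drp)), 0L)

  kb <- mergeEdgeLists(conf, conflictPolicy = "keep_both")
  expect_equal(nrow(edgeTable(kb)), 2L)
  expect_equal(as.numeric(signedAdjacency(kb)["A", "B"]), 0)

  expect_error(mergeEdgeLists(list()), "at least one")
})

test_that("merge conserves every input row and S/B agree in support", {
  set.seed(42)
  for (rep in 1:20) {
    nRows <- sample(5:40, 1)
    nodes <- sprintf("x%d", 1:6)
    raw <- data.frame(source = sample(nodes, nRows, TRUE),
                      target = sample(nodes, nRows, TRUE),
                      sign = sample(c(-1L, 1L), nRows, TRUE))
    net <- mergeEdgeLists(list(raw), conflictPolicy = "ambiguous")
    a <- auditLog(net)
    expect_identical(
      nrow(edgeTable(net)) + a$duplicates + a$selfLoops + a$ambiguousRows,
      a$inputRows)
    expect_identical(a$ambiguousRows, 2L * nrow(ambiguousPairs(net)))
    S <- signedAdjacency(net)
    B <- unsignedAdjacency(net)
    expect_true(all((S != 0) == (B == 1)))
    expect_equal(abs(as.matrix(S)), as.matrix(B), ignore_attr = TRUE)
  }
})

test_that("giant component keeps the largest component with lexicographic ties", {
  el <- data.frame(source = c("A", "B", "D"), target = c("B", "C", "E"),
                   sign = 1L)
  gc <- giantComponent(mergeEdgeLists(list(el)))
  expect_equal(geneIds(gc), c("A", "B", "C"))

  single <- mergeEdgeLists(list(el[1:2, ]))
  expect_equal(geneIds(giantComponent(single)), geneIds(single))

  tie <- data.frame(source = c("C", "A"), target = c("D", "B"), sign = 1L)
  gc <- giantComponent(mergeEdgeLists(list(tie)))
  expect_equal(geneIds(gc), c("A", "B"))
})

test_that("diameter and radius match hand-enumerable eccentricities", {
  path3 <- mergeEdgeLists(list(
    data.frame(source = c("A", "B"), target = c("B", "C"), sign = 1L)))
  expect_equal(networkMetrics(path3)[c("diameter", "radius")],
               list(diameter = 2L, radius = 1L))

  triangle <- mergeEdgeLists(list(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
               sign = 1L)))
  expect_equal(networkMetrics(triangle)[c("diameter", "radius")],
               list(diameter = 1L, radius = 1L))

  path5 <- mergeEdgeLists(list(
    data.frame(source = c("A", "B", "C", "D"),
               target = c("B", "C", "D", "E"), sign = 1L)))
  m <- networkMetrics(path5)
  expect_equal(m$diameter, 4L)
  expect_equal(m$radius, 2L)

  expect_error(networkMetrics(mergeEdgeLists(list(
    data.frame(source = "A", target = "B", sign = 1L)[0, ]))),
    "empty")
})

test_that("metrics agree with a brute-force BFS all-pairs oracle", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    edges <- randomSignedEdges(n, sample(n:(3 * n), 1))
    net <- edgesToNetwork(edges)
    got <- networkMetrics(net)
    want <- oracleMetrics(edgeTable(net), geneIds(net))
    expect_identical(got, want)
  }
})

test_that("network export round-trips through readEdgeList", {
  el <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   sign = c(1L, -1L))
  net <- mergeEdgeLists(list(el))
  p <- tempfile(fileext = ".tsv")
  writeEdgeList(net, p)
  back <- readEdgeList(p)
  expect_equal(back[, c("source", "target", "sign")],
               edgeTable(net)[, c("source", "target", "sign")])
})
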