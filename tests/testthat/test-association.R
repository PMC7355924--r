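pv <- function(x, y, dataset = "d") list(dataset = dataset, x = x, y = y,
                                         n = length(x))

test_that("correlation coefficients and p-values follow the closed forms", {
  expect_equal(correlatePair(pv(c(1, 2, 3), c(2, 4, 6)))$r, 1)
  expect_equal(correlatePair(pv(c(1, 2, 3), c(3, 2, 1)))$r, -1)

  # r = 0.8 by hand: cov = 3.2, var_x = var_y = 2.5 (n-1 denominators)
  res <- correlatePair(pv(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)))
  expect_equal(res$r, 0.8)
  tstat <- 0.8 * sqrt(3) / sqrt(1 - 0.8^2)
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)

  expect_error(correlatePair(pv(c(1, 2), c(3, 4))), "more than two")
  const <- correlatePair(pv(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(const$r))
  expect_equal(const$reason, "constant_vector")
})

test_that("Pearson p-values match the t transform on random vectors", {
  set.seed(11)
  for (n in c(5, 10, 30)) {
    x <- rnorm(n); y <- rnorm(n)
    res <- correlatePair(pv(x, y))
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    expect_equal(res$r, r, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(tstat), df = n - 2), tolerance = 1e-10)
  }
})

test_that("Spearman equals Pearson on ranks when there are no ties", {
  set.seed(12)
  x <- rnorm(12); y <- rnorm(12)
  sp <- correlatePair(pv(x, y), method = "spearman")
  pr <- correlatePair(pv(rank(x), rank(y)), method = "pearson")
  expect_equal(sp$r, pr$r, tolerance = 1e-12)
})

test_that("all three methods agree in sign on noiseless monotone data", {
  x <- c(0.3, 1.1, 2.2, 3.5, 4.1, 5.9, 7)
  for (y in list(exp(x), -log(x + 1))) {
    rs <- vapply(c("pearson", "spearman", "kendall"), function(m)
      correlatePair(pv(x, y), method = m)$r, numeric(1))
    expect_true(all(sign(rs) == sign(rs[1])))
    expect_equal(abs(rs[["spearman"]]), 1)
  }
})

test_that("pair assessment aggregates per-dataset results as documented", {
  genes <- c("a", "b")
  mk <- function(xy, id) {
    m <- rbind(a = xy$x, b = xy$y)
    colnames(m) <- paste0(id, seq_along(xy$x))
    m
  }
  # single dataset: identity aggregation
  set.seed(4)
  x <- rnorm(10); y <- x + rnorm(10, sd = 0.2)
  coll1 <- ExpressionCollection(list(d1 = mk(list(x = x, y = y), "s")))
  a1 <- assessPair("a", "b", coll1)
  single <- correlatePair(pv(x, y))
  expect_equal(a1$combinedR, single$r)
  expect_equal(a1$combinedP, single$p)
  expect_true(a1$homogeneous)

  # opposing signs across datasets: heterogeneous, filtered out
  coll2 <- ExpressionCollection(list(
    d1 = mk(list(x = x, y = y), "s"),
    d2 = mk(list(x = x, y = -y), "t")))
  a2 <- assessPair("a", "b", coll2)
  expect_false(a2$homogeneous)
  expect_equal(a2$status, "heterogeneous")

  # weighted mean of r: (10*r1 + 30*r2) / 40
  set.seed(5)
  x1 <- rnorm(10); y1 <- 0.6 * x1 + rnorm(10)
  x2 <- rnorm(30); y2 <- 0.9 * x2 + rnorm(30, sd = 0.3)
  coll3 <- ExpressionCollection(list(
    d1 = mk(list(x = x1, y = y1), "s"),
    d2 = mk(list(x = x2, y = y2), "t")))
  a3 <- assessPair("a", "b", coll3)
  r1 <- correlatePair(pv(x1, y1))$r
  r2 <- correlatePair(pv(x2, y2))$r
  expect_equal(a3$combinedR, (10 * r1 + 30 * r2) / 40, tolerance = 1e-12)
  p1 <- correlatePair(pv(x1, y1))$p
  p2 <- correlatePair(pv(x2, y2))$p
  expect_equal(a3$combinedP,
               pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # max-n policy: the biggest dataset speaks
  a4 <- assessPair("a", "b", coll3, aggregate = "max_n")
  expect_equal(a4$combinedR, r2)
  expect_equal(a4$combinedP, p2)
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.5), 0.5)
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdrAdjust(c(0.1, 1.2)), "0, 1")
  expect_error(fdrAdjust(numeric()), "empty")
})

test_that("sign categories and edge coherency follow the classification rules", {
  expect_equal(classifySignCategory(0.5, 0.01), "positive")
  expect_equal(classifySignCategory(-0.5, 0.03), "negative")
  expect_equal(classifySignCategory(0.9, 0.06), "non_significant")
  expect_equal(classifySignCategory(0.9, 0.05), "non_significant")  # boundary

  expect_equal(classifyEdgeCoherency(1L, "positive"), "coherent")
  expect_equal(classifyEdgeCoherency(-1L, "positive"), "incoherent")
  expect_equal(classifyEdgeCoherency(1L, "negative"), "incoherent")
  expect_equal(classifyEdgeCoherency(-1L, "negative"), "coherent")
  expect_equal(classifyEdgeCoherency(1L, "non_significant"),
               "non_significant")
})

test_that("flipping the edge sign swaps coherent and incoherent", {
  for (cat in c("positive", "negative", "non_significant")) {
    a <- classifyEdgeCoherency(1L, cat)
    b <- classifyEdgeCoherency(-1L, cat)
    if (cat == "non_significant") {
      expect_equal(a, b)
    } else {
      expect_setequal(c(a, b), c("coherent", "incoherent"))
    }
  }
})

test_that("DEG truth table has exactly four coherent and four incoherent cells", {
  tt <- degCoherencyTable()
  expect_equal(nrow(tt), 8L)
  expect_equal(sum(tt$call == "coherent"), 4L)
  expect_equal(sum(tt$call == "incoherent"), 4L)

  expect_equal(classifyDegCoherency("up", "up", 1L), "coherent")
  expect_equal(classifyDegCoherency("up", "up", -1L), "incoherent")
  expect_equal(classifyDegCoherency("up", "down", -1L), "coherent")
  expect_error(classifyDegCoherency("up", NA, 1L), "label")
  expect_error(classifyDegCoherency("up", "flat", 1L), "up")
})

test_that("associatePairs runs one BH family over the scorable pairs", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:8)
  m <- matrix(rnorm(8 * 12), 8, dimnames = list(genes, paste0("s", 1:12)))
  m["g02", ] <- 2 * m["g01", ] + rnorm(12, sd = 0.1)   # strong planted pair
  coll <- ExpressionCollection(list(d = m))
  pairs <- data.frame(geneI = genes[c(1, 3, 5, 7)],
                      geneII = genes[c(2, 4, 6, 8)],
                      sign = c(1L, 1L, -1L, 1L))
  res <- associatePairs(pairs, coll)
  ok <- res$status == "ok"
  expect_equal(res$q[ok], p.adjust(res$combined_p[ok], "BH"))
  expect_equal(res$category[res$geneI == "g01"], "positive")
  expect_equal(res$coherency_call[res$geneI == "g01"], "coherent")
  # a pair absent from the data is ineligible, never classified
  res2 <- associatePairs(data.frame(geneI = "g01", geneII = "nope"), coll)
  expect_equal(res2$status, "ineligible")
  expect_true(is.na(res2$category))
})
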