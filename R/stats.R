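#' Per-class ratio table of correlation categories
#'
#' Aggregates classified pairs into one row per subgraph class with counts
#' of positive / negative / non-significant categories (and coherent /
#' incoherent calls where an edge sign exists) plus the corresponding
#' proportions. The UGP row pools the counts over all replicates; its
#' proportions are the average of the per-replicate proportions (identical
#' to the pooled proportions when replicate sizes are equal), and the
#' per-replicate counts are retained in the `"ugpReplicates"` attribute.
#'
#' @param classified data.frame with columns `class`, `category` and
#'   optionally `coherency_call` and `replicate` (used for rows with class
#'   `"UGP"`). Rows with `NA` category (unclassifiable pairs) are ignored.
#' @param classes optional character vector fixing the row set; classes
#'   absent from the data get a flagged zero row.
#' @return data.frame with columns `class`, `n_total`, `n_positive`,
#'   `n_negative`, `n_nonsig`, `n_coherent`, `n_incoherent`,
#'   `prop_positive`, `prop_negative`, `prop_nonsig`, `prop_coherent`,
#'   `flag_empty`.
#' @export
buildRatioTable <- function(classified, classes = NULL) {
  stopifnot(all(c("class", "category") %in% names(classified)))
  d <- classified[!is.na(classified$category), , drop = FALSE]
  if (is.null(classes)) classes <- unique(classified$class)
  rows <- lapply(classes, function(cl) {
    di <- d[d$class == cl, , drop = FALSE]
    nTot <- nrow(di)
    nPos <- sum(di$category == "positive")
    nNeg <- sum(di$category == "negative")
    nNon <- sum(di$category == "non_significant")
    hasCall <- "coherency_call" %in% names(di) && nTot > 0 &&
      !all(is.na(di$coherency_call))
    nCoh <- if (hasCall) sum(di$coherency_call == "coherent", na.rm = TRUE)
            else NA_integer_
    nInc <- if (hasCall) sum(di$coherency_call == "incoherent", na.rm = TRUE)
            else NA_integer_
    if (cl == "UGP" && "replicate" %in% names(di) && nTot > 0) {
      byRep <- split(di, di$replicate)
      pp <- vapply(byRep, function(z)
        c(mean(z$category == "positive"), mean(z$category == "negative"),
          mean(z$category == "non_significant")), numeric(3))
      props <- rowMeans(pp)
    } else {
      props <- if (nTot) c(nPos, nNeg, nNon) / nTot else c(NA_real_, NA, NA)
    }
    data.frame(class = cl, n_total = nTot, n_positive = nPos,
               n_negative = nNeg, n_nonsig = nNon,
               n_coherent = nCoh, n_incoherent = nInc,
               prop_positive = props[1], prop_negative = props[2],
               prop_nonsig = props[3],
               prop_coherent = if (!is.na(nCoh) && nTot) nCoh / nTot
                               else NA_real_,
               flag_empty = nTot == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if ("UGP" %in% classes && "replicate" %in% names(d)) {
    du <- d[d$class == "UGP", , drop = FALSE]
    if (nrow(du)) {
      reps <- lapply(split(du, du$replicate), function(z)
        data.frame(replicate = z$replicate[1], n_total = nrow(z),
                   n_positive = sum(z$category == "positive"),
                   n_negative = sum(z$category == "negative"),
                   n_nonsig = sum(z$category == "non_significant")))
      attr(out, "ugpReplicates") <- do.call(rbind, c(reps,
                                                     make.row.names = FALSE))
    }
  }
  out
}

#' Pooled two-sample proportion (binomial proportion) test
#'
#' The standard pooled z-test of H0: p1 = p2, with
#' z = (k1/n1 - k2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2)) where
#' phat = (k1 + k2)/(n1 + n2), and a two-sided normal p-value. No continuity
#' correction by default (note `stats::prop.test` applies Yates' correction
#' unless told otherwise); set `correct = TRUE` to subtract
#' 0.5 (1/n1 + 1/n2) from |difference|.
#'
#' Degenerate pooled proportions (0 or 1) force both sample proportions to
#' be equal, so the test returns z = 0, p = 1 with `degenerate = TRUE`.
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @param correct apply continuity correction.
#' @return list with `z`, `p`, `estimate1`, `estimate2`, `degenerate`.
#' @export
twoProportionTest <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  phat <- (k1 + k2) / (n1 + n2)
  if (phat == 0 || phat == 1)
    return(list(z = 0, p = 1, estimate1 = p1, estimate2 = p2,
                degenerate = TRUE))
  d <- p1 - p2
  if (correct) d <- sign(d) * max(0, abs(d) - 0.5 * (1 / n1 + 1 / n2))
  z <- d / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), estimate1 = p1, estimate2 = p2,
       degenerate = FALSE)
}

#' All pairwise class-proportion comparisons
#'
#' Runs the pooled two-proportion test on every pair of classes with
#' non-empty rows, comparing the chosen proportion (`positive` by default;
#' `negative`, or `coherent` restricted to classes that carry coherency
#' calls), and adjusts the whole comparison family with Benjamini-Hochberg.
#' The UGP row enters with its pooled replicate counts.
#'
#' @param ratioTable output of [buildRatioTable()].
#' @param proportion which per-class proportion to compare.
#' @param correct continuity correction, see [twoProportionTest()].
#' @return data.frame with columns `classA`, `classB`, `k1`, `n1`, `k2`,
#'   `n2`, `z`, `p`, `q`.
#' @export
compareAllClasses <- function(ratioTable,
                              proportion = c("positive", "negative",
                                             "coherent"),
                              correct = FALSE) {
  proportion <- match.arg(proportion)
  col <- switch(proportion, positive = "n_positive",
                negative = "n_negative", coherent = "n_coherent")
  rt <- ratioTable[ratioTable$n_total > 0, , drop = FALSE]
  if (proportion == "coherent")
    rt <- rt[!is.na(rt$n_coherent), , drop = FALSE]
  if (nrow(rt) < 2)
    stop("need at least two non-empty classes to compare")
  cmb <- utils::combn(nrow(rt), 2)
  rows <- apply(cmb, 2, function(ix) {
    a <- rt[ix[1], ]; b <- rt[ix[2], ]
    tt <- twoProportionTest(a[[col]], a$n_total, b[[col]], b$n_total,
                            correct = correct)
    data.frame(classA = a$class, classB = b$class,
               k1 = a[[col]], n1 = a$n_total, k2 = b[[col]], n2 = b$n_total,
               z = tt$z, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdrAdjust(out$p)
  rownames(out) <- NULL
  out
}
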