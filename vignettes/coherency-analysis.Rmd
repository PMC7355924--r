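---
title: "Coherency analysis of signed signaling networks against expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherency analysis of signed signaling networks against expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coherNet)
```

## The question and the model

A curated signaling network asserts *causal signs*: gene I activates or
inhibits gene II. Transcriptomics observes *correlations*. coherNet asks how
often the two agree. A directly connected pair is **coherent** when its
expression correlation is significant and matches the edge sign (activation
with positive correlation, inhibition with negative), **incoherent** when
the significant correlation contradicts the sign, and **non-significant**
otherwise. The same logic applies to differential-expression flags: an
activation edge with both genes moving in the same direction (up/up or
down/down) is coherent, an inhibition edge is coherent when they move
oppositely — exactly four of the eight (direction, direction, sign)
combinations are coherent.

Because connected pairs could correlate for many uninteresting reasons, the
reference class is **unconnected gene pairs (UGPs)**: pairs with no directed
path between them in either orientation. Per-class proportions of
positive/negative/non-significant calls are compared with a pooled
two-proportion z-test.

## The pipeline, stage by stage

1. **Network assembly.** Signed edge lists (3-column TSV or SIF) are merged
   into a `SignedNetwork`. Self-loops are dropped (a self-loop has no pair
   correlation) and exact duplicates collapsed; both are counted, and the
   audit identity *edges + duplicates + self-loops + ambiguous rows = input
   rows* is enforced by tests. An ordered pair carrying **both** signs after
   the merge cannot be scored for coherency; the default policy removes it
   to a separate ambiguous-pair table (`keep_both` and `drop` are
   available, because curated pathway sets do not document how such
   conflicts should be reconciled). Node order is lexicographic so adjacency
   matrices and downstream indices are reproducible.

2. **Eligibility.** Expression datasets are analyzed strictly separately —
   pooling samples from different studies and platforms would manufacture
   or destroy correlations. A dataset contributes to a pair only when both
   genes are measured and **more than two** complete-case samples remain
   (`minN = 3`); a pair is eligible when at least one dataset contributes.
   Missing values are handled complete-case within the pair, since
   correlation needs paired observations.

3. **Correlation and homogeneity.** Per contributing dataset, Pearson (p
   from the exact t transform with n−2 df), Spearman, or tie-corrected
   Kendall tau-b. A pair is **homogeneous** when all defined nonzero
   per-dataset coefficients share one sign (r = 0 is sign-neutral);
   heterogeneous pairs are filtered out rather than averaged into a
   meaningless compromise. Datasets where either vector is constant have no
   defined correlation and are excluded with a logged reason.

4. **Aggregation.** Nothing in the underlying design dictates how several
   dataset-level correlations become one edge-level call, so the policy is
   explicit and configurable: the default combines r as the
   sample-size-weighted mean and p by Fisher's method on the two-sided
   p-values (a single dataset keeps its own values); `max_n` lets the
   largest dataset speak alone.

5. **FDR and classification.** One Benjamini–Hochberg family per analysis
   run covers all scorable (eligible, homogeneous) edges; the UGP pairs of
   a run form their own family, since they are a separately sampled
   population. Significance is `q < alpha` (default 0.05, the conventional
   cutoff); the sign of the combined r then yields
   positive/negative/non-significant, and the edge sign converts that to
   coherent/incoherent/non-significant.

6. **Subgraph census.** Two-node loops are read straight off the edge table
   (both directions present): both activating → DPFBL1, both inhibiting →
   DPFBL2, mixed → DNFBL. Multi-edge classes come from signed
   adjacency-matrix powers: `signedPower(S, k)[i, j]` sums walk
   sign-products, `unsignedPower(B, k)` counts walks (powers count *walks*,
   with revisits — that is what matrix self-multiplication does, and the
   test oracle enumerates walks accordingly). For each direct edge the
   shortest indirect walk of length 2…radius (return walk → feedback,
   parallel walk → feed-forward) supplies the indirect sign, accepted only
   when all walks at that length agree (`|signed| = count`); sign-mixed
   pairs are excluded because a class label needs a single net sign. The
   (direct, indirect) sign → label map lives in `motifClassMap()` as data,
   not code: the naming convention (negative loop product → "MN…",
   agreeing feed-forward legs → "MFFL") is an interpretation, and a
   different convention can be swapped in without touching the census.
   Classes deliberately overlap (a dual-loop edge still counts under
   Act/Inh), so per-class tallies are reported independently.

7. **UGP sampling.** Candidates are unordered pairs unreachable in *both*
   directions. The adjacency matrix is self-multiplied beyond the network
   diameter; the default horizon is n−1, i.e. the full directed transitive
   closure, because directed path lengths can exceed the undirected
   diameter and `reachability()` stops at the fixpoint anyway, so the safe
   horizon costs nothing. Ambiguous-sign pairs are excluded (connected,
   merely unsigned), and candidates must be expression-eligible so the
   identical downstream analysis runs on every sampled pair. The design is
   10 replicates of 1000 pairs; replicate seeds derive deterministically
   from the master seed.

8. **Ratios and proportion tests.** `buildRatioTable()` keeps the
   conservation identity (positive + negative + non-significant = total)
   per class; the UGP row pools replicate counts and averages per-replicate
   proportions (identical when replicate sizes are equal, and the
   per-replicate counts are retained for inspection).
   `twoProportionTest()` is the pooled z-test without continuity
   correction by default — note `stats::prop.test` applies Yates'
   correction unless told otherwise, which is why the closed form is
   implemented directly and cross-checked against `prop.test(correct =
   FALSE)` in the tests. All pairwise class comparisons form one BH family.
   Which proportion is compared (positive, negative, or coherent) is an
   explicit option, defaulting to positive, which is defined for every
   class including UGP.

## The synthetic-data generator

`simulateStudy()` provides data with known answers. The generator's
defaults are the package's validation conditions: 200 random edges over 150
genes, activation probability 0.72 (the activation share typical of curated
signaling edge lists), six injected two-node loops and eight injected
triangles covering every motif class, five independent datasets of 20
samples, planted coherent fraction φ = 0.8, effect size β = 1, noise sd
σ = 0.5, and 5% per-dataset gene missingness.

Expression follows a linear-Gaussian model because the pipeline's statistic
is correlation — any monotone response would do, but the linear form gives
closed-form expectations (a noiseless single-parent coherent edge has
r exactly ±1; independent pairs have sd(r) ≈ 1/√(n−1)). Per dataset, every
gene starts as an independent standard normal; each effect target is then
overwritten by the sum of its parents' signed contributions plus noise.
Coherent edges use the edge sign; incoherent edges use the flipped sign
(`anti_sign`, the default, which yields sharp recovery tests) or no effect
at all (`independent`, emulating null-like real edges). Targets are
processed in a Kahn-style dependency order with cycles broken at the
lexicographically smallest remaining gene, whose unresolved parents enter
with their initial values — a single deterministic Gauss–Seidel-style pass.

DEG labels are generated edge-by-edge: unlabeled sources get random
up/down, unlabeled targets realize the edge's planted status under the
truth-table rule. A target that already carries a label keeps it, so edges
sharing a target realize coherency only by chance; recovery of φ therefore
degrades with graph density, and the recovery test runs in a sparse,
near-collision-free regime (500 edges over 50,000 genes).

What the generator does **not** emulate: platform-specific noise,
batch effects, probe-level artifacts, heavy-tailed expression, or
realistic degree distributions. Passing tests demonstrate that the
machinery is correct and calibrated under the stated model, not that any
biological network is coherent.

## Numerical and degenerate-input choices

- Fisher's combination guards `log(0)` by flooring p at the smallest
  positive double.
- Pairs whose eligible datasets are all zero-variance produce no usable
  correlation and are counted with the ineligible in the filter funnel, so
  *total = ineligible + heterogeneous + coherent + incoherent +
  non-significant* holds exactly.
- Degenerate pooled proportions (0 or 1) force equal sample proportions,
  so the proportion test returns z = 0, p = 1 with a flag.
- Giant-component ties break toward the component containing the
  lexicographically smallest gene.
- A pipeline rerun under the same config and seed is byte-identical: the
  report bundle carries no timestamps, and every random draw (network,
  expression, labels, UGP replicates) derives from the master seed.

## Problem sizes used in validation

The bundled tests run the full pipeline at the default study conditions
(including the 1000 × 10 UGP design), motif-census equivalence against a
brute-force walk enumerator on 100 random graphs of up to 15 nodes and 40
edges at walk lengths up to 5, screening calibration on 1000 independent
pairs of 30 samples, and proportion-test calibration on 10,000 null
replicates at n = 500 per group — sizes at which the Monte-Carlo error of
the calibrated rates is a few tenths of a percent.

## Worked example

```{r example, eval = FALSE}
library(coherNet)

study <- simulateStudy(simulationConfig(seed = 1))
res <- runPipeline(runConfig(network = study$network,
                             expression = study$expression, seed = 1))

res$metrics            # giant component size, diameter, radius
res$funnel             # edge filter funnel (conserved exactly)
res$ratioTable         # per-class category counts and proportions
subset(res$proportionTests, classB == "UGP")
```

## Known limitations

- Correlation is the only association measure, by design; no partial
  correlations or information-theoretic scores.
- The motif class map encodes one naming convention for the
  feedback/feed-forward sign combinations; it is configurable data because
  the convention, not the census machinery, is the assumption.
- The aggregation of per-dataset correlations into one edge-level call is a
  policy choice (weighted mean + Fisher), not a uniquely determined rule;
  `max_n` is provided and both are recorded in the run summary.
- Heterogeneous pairs are removed, not modeled; with many datasets and weak
  effects this filter is conservative and, for null pairs, strongly
  selective (a null pair passes it with probability ~2^(1−d) for d
  datasets), which is why UGP calls are reported within their own FDR
  family.
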