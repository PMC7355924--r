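Package: coherNet
Title: Coherency Analysis of Signed Signaling Networks Against Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether the sign of causal edges in a directed signed
    signaling network (activation/inhibition, plus two-node and multi-edge
    feedback and feed-forward subgraph classes) is consistent with pairwise
    gene-expression correlations observed across independent expression
    datasets, against a null of unconnected gene pairs. Provides signed
    edge-list import and merging, structural metrics (giant component,
    diameter, radius), per-dataset correlation with homogeneity filtering
    and Benjamini-Hochberg adjustment, coherency classification from
    correlations or differential-expression labels, a subgraph census via
    signed adjacency-matrix powers, unconnected-gene-pair sampling, pooled
    two-proportion tests across subgraph classes, a synthetic-data generator
    with planted coherency for validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
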