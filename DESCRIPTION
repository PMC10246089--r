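Package: mlcoex
Title: Multilayer Community Detection in Tissue Co-Expression Correlation Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects gene communities directly from tissue-specific gene
    co-expression correlation matrices viewed as a multiplex network with
    diagonal categorical interlayer couplings. Implements a maximum-entropy
    configuration-model null for correlation matrices, multilayer modularity
    maximization by generalized Louvain with iteration and consensus
    clustering, resolution-parameter selection by the one-dimensional convex
    hull of admissible partitions, closed-form Z-scores for community
    intralayer weight under the null, specialist/generalist community
    classification, permutation tests for chromosomal localization of
    community genes, shared cis-eQTL pair discovery, and a synthetic-data
    generator with planted community structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    withr
Config/testthat/edition: 3
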