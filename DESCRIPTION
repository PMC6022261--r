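Package: meripModules
Title: Reliability-Weighted Clustering for Epitranscriptome Module
    Detection from MeRIP-Seq Count Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects epitranscriptome modules (groups of RNA m6A
    methylation sites that co-vary across experimental conditions) from
    MeRIP-seq IP/input read counts. Methylation levels estimated from
    low-coverage sites are unreliable, so pairwise distances between
    methylation profiles are computed with per-measurement reliability
    weights derived from read coverage (logarithm-based or
    threshold-based schemes) before hierarchical clustering. Includes a
    sample-label clustering benchmark with an exact-match criterion, a
    two-dimensional grid search over the weighting parameters, one-sided
    hypergeometric module-significance scoring against random modules,
    and a seeded generator of MeRIP-seq-like count data with planted
    modules and heterogeneous coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    limma,
    cluster,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
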