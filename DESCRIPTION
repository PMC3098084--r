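Package: clustgrid
Title: Benchmarking Class Discovery Pipelines for Two-Channel Microarray Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating complete cluster-analysis pipelines on
    two-channel (common reference) microarray experiments. Covers MA-loess
    normalization (global and print-tip, with and without background
    correction), flag/threshold filtration, missing-value imputation (row
    median and iterative SVD), unsupervised and supervised gene selection,
    z-standardization, eleven clustering methods, and evaluation of predicted
    partitions against known classes via the adjusted Rand index with an
    optimal ten-to-two cluster merge. A synthetic-data generator produces
    realistic common-reference experiments with planted class structure so
    that the full factorial method grid, its variance decomposition and the
    iterative pairwise-Wilcoxon method elimination can be exercised and tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    mclust
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
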