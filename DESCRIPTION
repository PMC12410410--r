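Package: aigps
Title: Adaptive Individualized Gene-Pair Signatures for Transcriptomic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts gene-expression matrices into ternary reversal-coded
    gene-pair features using a per-pair adaptive difference threshold derived
    from the Welch-Satterthwaite statistic, screens pairs across phenotype
    classes with Fisher's exact or Pearson's chi-squared tests, trains and
    prunes random-forest gene-pair signatures, and provides evaluation
    metrics, odds-based survival risk stratification, and gene-pair network
    construction. Includes a multi-cohort synthetic expression-data generator
    with planted pair reversals and batch shifts, and a command-line
    interface orchestrating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    survival,
    igraph,
    e1071,
    nnet,
    class,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
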