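Package: recalvg
Title: Recalibrating Differential Expression Fold Changes by Genetic Dosage Variance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rescales nominal differential-expression log fold changes by the
    standard deviation of genetically regulated gene expression (V^G), so that
    changes are expressed in units of natural population dosage variation.
    Includes a cross-tissue inference procedure that imputes missing
    tissue-specific V^G estimates from correlated tissues after adjusting for
    expression level, weighted harmonic-mean aggregation of V^G across tissues,
    hypergeometric over-representation comparison of nominal versus
    recalibrated gene selections, and a synthetic-data generator reproducing
    the statistical structure the method assumes. Reads and writes
    DESeq2-style result tables, gene-by-tissue TSV matrices, and GMT gene-set
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
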