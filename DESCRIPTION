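Package: epireversion
Title: Classification of Reversible and Irreversible Regulatory Changes
    After Transient Epigenetic Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for multi-omic classification of
    genes and chromatin regions as reversibly or irreversibly altered after
    a transient epigenetic perturbation (for example a pulsed RNAi
    knock-down of a Polycomb group subunit). Provides a simplified
    negative-binomial differential test, multi-layer self-organizing-map
    clustering of fold-change profiles, interval algebra for confident-peak
    consolidation and Polycomb-target classification, position-weight-matrix
    scanning with exact p-value score thresholds, LASSO-based motif effect
    models on chromatin accessibility, somatic-variant allele-fraction and
    sharing summaries, and a synthetic-data generator with planted ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
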