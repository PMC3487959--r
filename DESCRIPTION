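Package: antiprofiler
Title: Cancer Anti-Profiles from Gene Expression Hyper-Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene expression anti-profiles: signatures of genes that are
    hyper-variable across cancer samples relative to normal samples, each with a
    robust normal range of expression (median +/- k median absolute deviations).
    Samples are scored by counting signature genes whose expression falls outside
    the normal range, so classification is by deviation from, not similarity to,
    a profile. Includes variance-ratio gene selection for a single cancer/normal
    comparison and across many tissue and cancer types, candidate restriction to
    genomic blocks or tissue-specific genes, ROC/AUC evaluation, stratified
    k-fold and leave-one-tissue-out cross-validation, random-signature
    significance testing, and a synthetic-data generator with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    withr,
    optparse,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
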