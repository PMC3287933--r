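Package: SnpSetTest
Title: Joint Common and Rare Variant SNP-Set Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control association testing for SNP sets (genes) that jointly
    model common and rare variants. Implements Madsen-Browning weighted-sum
    collapsing of rare variants by functional class, a principal-fitted-components
    summary score for common variants, logistic-regression score tests with
    gene-environment interactions, logistic kernel machine variance-component
    score tests (linear and quadratic kernels) with scaled chi-square moment
    matching and a combined statistic, and a two-stage screening/testing pipeline
    with permutation p-values and Holm adjustment. Ships a synthetic exome-like
    case-control data generator with population structure for calibration and
    power experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
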