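Package: follsig
Title: Molecular Signature Discovery and Stage Prediction for Early
    Ovarian Folliculogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and using a transcriptomic signature of
    early ovarian follicular development from compartment-resolved
    (oocyte and granulosa cell) expression data. Provides a
    negative-binomial differential-expression engine with exact
    conditional pairwise tests and likelihood-ratio stage tests,
    fold-change and false-discovery-rate biomarker selection against a
    multi-tissue background, efficiency-corrected (Pfaffl) qPCR
    quantification with multi-reference normalization and geNorm-style
    reference stability ranking, a two-part (hurdle) hierarchical mixed
    model of expression presence and fourth-root level with correlated
    stage random effects, empirical-Bayes posterior prediction of
    follicular stage from new expression vectors, and a resampling study
    of predictive ability. A synthetic-data module emulates the
    stage-by-compartment laser-capture design so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
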