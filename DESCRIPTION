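Package: takcoex
Title: Gene Co-Expression Network Analysis of qPCR Panels for Disease
    Activity in Takayasu's Arteritis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing targeted RT-qPCR panels in small clinical
    cohorts: reference-gene stability assessment (geNorm, NormFinder,
    BestKeeper re-implementations), 2^-ddCq relative quantification,
    condition-wise gene co-expression networks with topology statistics,
    complete-linkage module extraction at fixed cut heights, a
    regression-residual (M-value) disease-activity scoring system with
    Youden-index thresholds and ROC summaries, a three-metric score of
    functional closeness between a gene set (e.g. Toll-like receptors) and
    the rest of the panel, and a miRNA-target network builder with family
    pooling.  Includes a synthetic cohort generator that emulates the
    two-block (TLR vs T-cell activation) correlation structure observed in
    Takayasu's arteritis, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
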