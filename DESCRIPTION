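Package: qtlmeta
Title: Tissue-Specific QTL Meta-Analysis on a Reference Genetic Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis of quantitative trait locus (QTL) reports across
    heterogeneous bi-parental mapping studies. Standardizes reported QTL
    statistics to a uniform LOD/R-squared/95% confidence-interval set using
    population-size based interval approximations, projects component genetic
    maps and their QTL onto a dense reference map through shared-marker
    homothetic rescaling, clusters projected QTL per chromosome into consensus
    meta-QTL with a fixed-variance Gaussian mixture fitted by EM and selected
    by five information criteria (AIC, AICc, AIC3, BIC, AWE), and summarizes
    genome coverage, coverage reduction, physical anchoring, and cross-tissue
    meta-QTL co-localization. Includes a synthetic multi-study data generator
    with known ground truth and a bundled catalog of published maize
    insect-resistance meta-QTL for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
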