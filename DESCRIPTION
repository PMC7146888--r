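Package: qtlmeta
Title: Meta-Analysis of Quantitative Trait Loci on a Consensus Genetic Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for meta-QTL analysis in crops. Builds a validated
    compendium of published QTL detections, estimates 95% confidence
    intervals from population design, size and explained variance, projects
    QTLs from heterogeneous linkage maps onto a consensus reference map by
    flanking-marker interpolation, clusters projected QTLs per trait and
    chromosome with Gaussian mixtures carrying observation-specific
    variances (model order chosen by a vote over AIC, AICc, AIC3, BIC and
    AWE), and reports consensus meta-QTLs with pooled confidence intervals.
    Meta-QTLs can be anchored to physical coordinates for gene enumeration,
    feature-track co-location and cross-species ortho-meta-QTL detection via
    ortholog pairs. A synthetic-compendium generator with known ground truth
    supports recovery benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
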