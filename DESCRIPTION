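Package: spliceodiv
Title: Splice-Variant Quantification, Splice-Site Strength Modelling, and
    Evolutionary Analysis of an Alternative Exon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising a species-specific alternative
    exon with competing 3' splice acceptors: quantifies splice-variant
    relative frequencies from junction-supporting read counts (with ANOVA
    and Bonferroni post hoc comparisons), fits maximum-entropy models of
    short splice-site motifs and scores candidate sites as log-odds
    splicing strengths, estimates pairwise evolutionary distances by a
    shared-parameter Tamura-Nei composite-likelihood method and builds
    Neighbor-Joining trees, and quantifies postsynaptic fluorescence
    line scans via a peak-restricted congruency ratio. A companion
    simulation module generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
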