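Package: cnascape
Title: Copy-Number Alteration Landscape Analysis for Segmented Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for segmented somatic copy-number profiles
    (SEG-like tables) of tumor cohorts: gain/loss state calling with fixed
    log2-ratio cutoffs, genome-wide frequency profiles on a 1-Mb bin grid,
    arm-level event calling and the arm gain/loss frequency correlation,
    copy-number breakpoint extraction with a permutation-based hotspot test,
    chromothripsis-like pattern scanning from copy-number status switches and
    a Poisson clustering likelihood ratio, and Ward hierarchical clustering of
    cohort copy-number matrices with clinical-label enrichment. Includes a
    seeded synthetic-cohort generator with ground truth so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    pheatmap,
    withr
Config/testthat/edition: 3
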