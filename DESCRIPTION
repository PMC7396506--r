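Package: chronolink
Title: Linking Colonic Microbiota Composition to Host Gene Expression
    Under a Two-Factor Circadian x Alcohol Design
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for integrating 16S rRNA OTU count tables
    with host gene expression count matrices measured on two unmatched
    cohorts sharing a 2x2 treatment design (alcohol x feeding time).
    Implements OTU-table preprocessing (lineage exclusion, rarefaction,
    rare-OTU filtering), community statistics (alpha diversity, Bray-Curtis
    dissimilarity, PERMANOVA with exhaustive or Monte Carlo permutations,
    centered log-ratio regressions with Benjamini-Hochberg control), a
    random-pairing correspondence procedure that matches samples across the
    two cohorts within treatment groups and counts per-pair significances
    against an exact binomial Bonferroni count threshold, two-step
    interaction regression models for taxon selection and gene-taxon
    association, and a synthetic two-cohort data generator with planted
    ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
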