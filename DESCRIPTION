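Package: mexscreen
Title: Behavioral and Whole-Brain Phenotyping for Zebrafish Microexon
    Mutant Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-throughput phenotyping screens of
    larval zebrafish mutant lines, built around three stages: behavioral
    profiling (movement-bout detection from delta-pixel traces, baseline
    frequency/magnitude/location measures, stimulus-response measures from
    high-speed burst recordings, Kruskal-Wallis group comparison and
    strictly standardized mean difference summarization), whole-brain
    voxel-wise activity and structure mapping (rank-sum Z maps with an
    empirically calibrated significance threshold targeting a fixed
    fraction of control voxels, signed significance maps, sum-of-slices
    projections, and atlas-region quantification), and microexon sequence
    utilities (length filter, peptide conservation statistics, upstream
    splice-regulatory layout classification, RT-PCR inclusion and
    delta-delta-Ct quantification with hierarchical clustering).  A
    synthetic-data module generates behavioral cohorts, brain-stack
    cohorts, labeled atlases, and microexon sequence sets with known
    planted effects so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
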