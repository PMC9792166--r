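Package: mrdtrack
Title: Tumor-Informed Circulating Tumor DNA Tracking for Minimal Residual
    Disease Monitoring
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for tumor-informed minimal residual disease (MRD)
    monitoring from ultra-deep amplicon sequencing of plasma cell-free DNA.
    Reads and filters tumor somatic-variant tables, summarizes the cohort
    mutational landscape (gene frequencies, mutation classes, co-occurrence
    and mutual exclusivity, hotspots), classifies variants against an
    editable drug-actionability rule table, ranks variants with a
    criterion-count scoring scheme to select a personalized tracking panel,
    calibrates a variant-allele-frequency limit of detection from titration
    series and healthy-donor panels, calls per-sample ctDNA positivity, and
    monitors longitudinal timelines for molecular relapse and lead time
    ahead of clinical diagnosis. Includes a seeded synthetic-data generator
    emulating the statistical structure of a colorectal-cancer MRD cohort
    so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
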