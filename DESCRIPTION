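Package: spermethylome
Title: Longitudinal Sperm DNA Methylome Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal sperm DNA methylation
    cohorts assayed on beta-value methylation arrays or capture bisulfite
    sequencing. Provides imprinting-control-region quality control with a
    closed-form somatic-contamination estimator, cross-cohort per-probe
    one-way ANOVA with Tukey-Kramer post hoc testing and top-k signature
    clustering, merging of significant CpG sites into differentially
    methylated regions, within-subject longitudinal alteration counting
    against a delta-beta cutoff, dynamic-CpG classification and enrichment
    testing, and a calibrated synthetic-cohort generator with ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
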