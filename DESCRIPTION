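Package: chorioscreen
Title: Multi-Stage Drug-Repurposing Screen Analysis for Choriocarcinoma
    Viability Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing phenotype-based drug-repurposing screens in
    choriocarcinoma cell lines: blank/DMSO normalization of 96-well optical
    densities, per-cell-line z-scoring of library-wide growth inhibition,
    cancer-selective hit calling against a normal trophoblast control line,
    triplicate secondary screening against a cisplatin positive control,
    four-parameter logistic dose-response fitting with IC50 confidence
    intervals, rule-based candidate triage, and downstream quantifications
    (delta-delta-Ct relative expression, ellipsoid tumor volumes with
    growth-curve comparison, and immunohistochemistry positive-fraction
    statistics). A seeded synthetic-data module generates every input with
    known ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Software, CellBasedAssays, Pharmacogenomics, Regression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
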