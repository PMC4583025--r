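Package: gsvpipe
Title: Identification of GLUT4 Storage Vesicle Proteins from Immunoisolation Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for calling high-confidence resident proteins
    of GLUT4 storage vesicles (GSVs) from comparative immunoisolation label-free
    quantitative (LFQ) proteomics. Implements median-absolute-deviation
    normalization of log2 intensities, left-censored multiple imputation anchored
    at the per-condition minimum, an empirical-Bayes moderated t-test per membrane
    preparation, directional (quadrant) integration of Z-scores across
    preparations, and a three-criteria classification (enrichment over IgG,
    abundance above the population median, insulin responsiveness). Includes a
    synthetic-data generator with known ground truth so every stage is testable,
    and a command-line driver for config-driven runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
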