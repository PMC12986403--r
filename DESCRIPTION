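Package: astigvec
Title: Alpins Astigmatism Vector Analysis and Standardized Outcome Tables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the seven standard Alpins vector metrics for astigmatism
    correction outcomes (target-induced astigmatism, surgically induced
    astigmatism, difference vector, correction index, magnitude of error,
    angle of error, and index of success) from 12-column refraction or
    corneal-astigmatism spreadsheets. Handles negative-to-positive cylinder
    transposition, spectacle-to-corneal vertex correction, and double-angle
    vector arithmetic; applies the standard low-TIA and missing-data
    exclusion rules; summarizes cohorts (means, standard deviations,
    geometric means, clinically relevant proportions); and runs
    normality-gated parametric or nonparametric two-group comparisons with
    Cohen's d effect sizes. Renders the standardized publication table as a
    high-resolution TIFF with machine-readable CSV and JSON exports, and
    includes a synthetic-cohort simulator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    readxl,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
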