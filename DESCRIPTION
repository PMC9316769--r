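Package: phytoqc
Title: Desirability-Based Response Surface Optimization and Chromatographic
    Quality Control for Herbal Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-compound quality control of herbal extracts:
    Box-Behnken experimental designs with coded/actual factor levels,
    overall-desirability (OD) aggregation of multiple quality indices,
    second-order response surface fitting with full lack-of-fit ANOVA,
    bounded maximization of the fitted surface, UHPLC calibration and
    method-validation statistics (linearity, LOD/LOQ, RSD, spike recovery),
    peak-area to content conversion with batch summaries, and seeded
    synthetic-data generators (designed-experiment responses, calibration
    points, variable-wavelength chromatograms) for end-to-end pipeline
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
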