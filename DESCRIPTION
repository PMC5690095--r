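Package: epidcal
Title: EPID Portal Dosimetry Calibration, Diagonal-Profile Correction, and
    Gamma-Index QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electronic portal imaging device (EPID) dosimetry
    quality assurance. Implements the Varian-style calibration chain
    (dark-field and flood-field correction, diagonal beam-profile
    restoration, calibrated-unit normalization), a one-dimensional
    off-axis response correction derived from the ratio of measured to
    predicted diagonal profiles via polynomial fitting, a global
    gamma-index comparator with pass-rate reporting, and a parametric
    synthetic EPID image simulator (beam horns, off-axis over-response,
    asymmetric support-arm backscatter, dark signal, noise) so the full
    workflow can be exercised and verified without measured linac data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
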