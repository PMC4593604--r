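Package: vmrstats
Title: Multivariate Statistics for Zebrafish Visual Motor Response Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for plate-based larval zebrafish visual
    motor response (VMR) experiments. Summarizes frame-level movement into
    per-second Burst Duration, extracts fixed-length activity windows around
    light-change events, compares activity profiles between groups with the
    two-sample Hotelling T-squared test under false-discovery-rate control,
    performs noncentral-F power analysis and minimal sample-size
    determination, fits multi-factor MANOVA models with sequential
    sums-of-squares-and-cross-products decomposition and the
    Pillai-Bartlett trace, and tracks per-second eta-squared effect-size
    dynamics. Ships a generative model of 96-well VMR plate experiments
    with AR(1) noise for calibration, power validation, and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
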