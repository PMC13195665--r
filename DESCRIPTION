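Package: thetakin
Title: Kinetic Inference for Time-Resolved Native Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting association and dissociation rate
    constants from time-resolved native mass spectrometry experiments
    performed with dual-channel (theta) electrospray emitters. An
    internal-standard nanobody-epitope "timer" pair with known kinetics
    calibrates the mixing time of every spectrum; ligand-bound fractions
    of the analyte are then fitted globally to a 1:1 reversible or
    irreversible binding model with per-burst mixing factors, nested-model
    F-tests, outlier-burst flagging and replicate aggregation. Includes a
    synthetic-data generator so every pipeline stage is testable by
    parameter recovery, plus ggplot2 visualisations and broom-style
    tidiers for fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
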