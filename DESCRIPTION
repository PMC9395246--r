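Package: nsindex
Title: Network State Index Classification of Cortical States from Local
    Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies cortical network states of wakefulness (delta-rhythmic
    versus nonrhythmic at graded activity levels) from extracellular local
    field potential (LFP) recordings via the Network State Index (NSI).
    Implements the Morlet-wavelet envelope machinery, the processed-LFP
    (pLFP) high-gamma envelope transform with noise-floor estimation, the
    signed NSI with episode-level validation, calibration of the frequency
    band, temporal smoothing and rhythmicity threshold against a reference
    membrane-potential signal, cross-validation of the LFP-based index
    against a membrane-potential-based index with a tolerance-box accuracy
    criterion, downstream distribution and regression analyses, and a
    synthetic paired LFP/membrane-potential recording generator with hidden
    ground-truth state schedules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
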