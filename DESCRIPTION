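Package: laserddr
Title: Femtosecond Laser Microirradiation Dosimetry and DNA Damage
    Response Recruitment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing femtosecond near-infrared
    laser microirradiation experiments on the DNA damage response (DDR).
    Converts instrument power settings into in-situ pulse energies and
    focal-spot peak irradiances, evaluates the photothermal and
    thermoelastic confinement calculus that distinguishes damage regimes,
    encodes measured recruitment thresholds and inhibitor epistasis as a
    rule-based predictor of DDR marker outcomes (53BP1, TRF2, PAR,
    gamma-H2AX and others), quantifies recruitment kinetics from
    fluorescence time-lapse stacks with ratio normalisation and
    exponential model fits, and generates seeded synthetic single-nucleus
    stripe-irradiation movies so the full pipeline is testable without
    external data.
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
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
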