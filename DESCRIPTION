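Package: thzcoag
Title: Terahertz Time-Domain Spectroscopy Analysis of Blood Coagulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for transmission terahertz
    time-domain spectroscopy (THz-TDS) of coagulating blood in a thin
    polyethylene-windowed fluidic chamber. Provides a synthetic cohort
    generator (double-Debye water baseline, red-blood-cell and
    platelet-dependent coagulation effects, instrument noise), the iterative
    Fresnel-corrected extraction of the complex refractive index and
    absorption constant from paired reference/sample field traces, and the
    cohort statistics used to characterise coagulation: pooled two-sample
    t-tests, Pearson correlations against hematology covariates, normalized
    absorption-change spectra, and transparency-frequency estimation with
    platelet stratification.
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
    signal,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
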