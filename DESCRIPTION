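Package: serovolt
Title: Serotonin Voltammetry Kinetics, Pharmacokinetics and Oscillation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo serotonin voltammetry. Simulates and
    fits a dual-uptake Michaelis-Menten model of evoked serotonin release and
    clearance (explicit-Euler forward solver, RMSE gradient-descent fitter with
    multi-start), couples it to a four-compartment pharmacokinetic model of
    intraperitoneal escitalopram through competitive-inhibition apparent-Km
    substitution, and processes fast-scan cyclic voltammetry (FSCV) colour
    plots and fast-scan controlled-adsorption voltammetry (FSCAV) basal
    series: frequency-domain Butterworth filtering, calibration, amplitude and
    half-life extraction, Simpson's-rule Faradaic charge integration with
    linear-regression calibration, bandpassing, autocorrelation,
    sliding-window correlation, Welch power spectral density and
    power-weighted mean frequency comparisons. A seeded synthetic-data
    generator supplies every input with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
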