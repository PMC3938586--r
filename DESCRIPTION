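Package: apopcal
Title: Populations of Cardiac Action Potential Models: Sweeps, Calibration and Conductance-Space Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing populations of paced cardiac
    action potential models. Provides a phenomenological six-conductance
    rabbit ventricular cell model, full-factorial conductance sweeps with
    steady-state detection, extraction of action potential and calcium
    transient biomarkers (dV/dt max, resting and plateau potentials, APD50,
    APD90, diastolic/systolic calcium, transient amplitude, CTD50, CTD90),
    calibration of the population against experimentally derived APD ranges
    at multiple cycle lengths, normalised root-mean-square deviation (NRMSD)
    goodness-of-fit ranking of biomarker combinations, and clutter-based
    dimension reordering for two-dimensional visualisation of the
    six-dimensional conductance space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
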