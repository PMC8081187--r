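Package: tactileP300
Title: Tactile P300 Brain-Computer Interface Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for two-class tactile P300
    brain-computer interfaces based on an oddball stimulation paradigm.
    Generates oddball stimulus schedules and synthetic multichannel EEG with
    planted P300 deflections and class-dependent lateralized band power;
    reads and writes BrainVision recordings; implements the standard ERP
    preprocessing chain (band-pass filtering, mastoid re-referencing,
    epoching with baseline correction, ICA-based ocular artifact removal);
    provides spectral analyses (Welch power spectral density, event-related
    spectral perturbation, inter-trial coherence, a delta/theta/alpha/beta
    filter bank with per-band classification scoring); fits Common Spatial
    Pattern filters with log-variance features; classifies with linear
    discriminant analysis or a radial-basis support vector machine under
    stratified cross-validation and sliding-window evaluation; and computes
    the Wolpaw information transfer rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
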