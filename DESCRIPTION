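Package: cardiowave
Title: Four-Compartment Haemodynamic Simulation and Arterial Waveform Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates arterial blood pressure with a four-compartment
    lumped-parameter (windkessel-type) model of the systemic circulation:
    an aortic exit region, the arterial tree, the venous pool and a left
    ventricle driven by a prescribed time-varying elastance. The model
    includes a pressure-dependent aortic valve, a Heaviside mitral valve,
    a Gaussian rebound impulse that shapes the dicrotic notch, and
    respiratory sinus arrhythmia modulating both heart rate and elastance
    amplitude. On top of the simulator the package provides beat-level
    waveform feature extraction, a perturbation sensitivity analysis that
    ranks parameters by their effect on arterial pressure, a staged
    parameter-estimation pipeline (finite-difference gradient descent on
    signal moments, Nelder-Mead refinement, and a coordinate search for
    the notch constants), and a pseudo-patient generator for testing
    fitting code without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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
NeedsCompilation: yes
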