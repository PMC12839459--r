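Package: neuromotor
Title: Evoked Motor Responses, Locomotor EMG, and Gait Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for neurophysiological assessment of motor function
    in non-human primate spinal-cord-injury studies: EMG conditioning (notch and
    band-pass filtering, rectification, envelope extraction), stimulus-triggered
    epoching of epidural-stimulation evoked responses with onset latency,
    peak-to-peak amplitude and a 3xSD response-presence criterion, recruitment
    curves and motor-threshold estimation, somatosensory evoked potential P1/N1
    features, antagonist-muscle coactivation (Rudolf) coefficients, and automated
    joint range-of-motion from goniograms. Ships seeded synthetic-recording
    generators with ground-truth sidecars so every stage is testable without
    animal data.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
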