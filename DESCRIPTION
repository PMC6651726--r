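Package: brakeintent
Title: EEG-Based Detection of Emergency Braking Intention While Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for decoding emergency braking intention from
    scalp EEG during simulated driving. Generates synthetic driving sessions
    (8-channel EEG at 128 Hz time-aligned with a 6-channel inertial
    measurement unit), labels training windows automatically from IMU
    standard-deviation thresholds, cleans artifacts with infomax independent
    component analysis gated by approximate entropy, extracts relative
    band-power and Burg autoregressive features, classifies with a
    three-layer perceptron (sigmoid hidden layer, softmax output,
    cross-entropy loss), and evaluates with stratified cross-validation,
    ROC/AUC, parameter sweeps and a simulated real-time sliding-window
    detector with lead-time measurement.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
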