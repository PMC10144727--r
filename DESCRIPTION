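Package: emgq
Title: Hand-Gesture Recognition from Surface EMG with Deep Q-Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: User-specific hand-gesture recognition from 8-channel surface
    electromyography (sEMG) sampled at 200 Hz, cast as a sequential decision
    problem. Recordings are segmented with a sliding window (length 300,
    stride 40), gated by relative window energy, and mapped to 40-dimensional
    time-domain feature vectors (absolute envelope, energy, RMS, standard
    deviation, mean absolute value per channel). A partially observable
    environment presents one recording per episode; from-scratch Deep
    Q-Network and Double Deep Q-Network agents (feed-forward or recurrent
    LSTM policies, experience replay, target network, Adam) learn to label
    windows, and majority-vote post-processing yields per-sample
    classification and recognition (temporal overlap) accuracy. Includes a
    seeded synthetic-cohort generator, dataset input/output in a plain-text
    per-user layout, sensor-orientation correction from "waveOut"
    synchronization samples, and a hyperparameter sweep utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
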