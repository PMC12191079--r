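Package: eegatt
Title: Attention-Driven Dynamic Graph Convolutional Networks for EEG Emotion
    Recognition
Version: 0.1.0
Authors@R:
    person("EEG", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Band-wise EEG feature extraction (differential entropy, band
    power spectral density, hemispheric and frontal-caudal asymmetries) and
    an attention-driven dynamic graph convolutional classifier with global
    attention pooling and gradient-reversal domain adaptation for
    cross-subject emotion recognition. Includes leave-one-subject-out and
    subject-dependent evaluation protocols, ablation variants, and a
    synthetic EEG generator with class effects and subject-level domain
    shift so the full pipeline is testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
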