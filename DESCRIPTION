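Package: prosodia
Title: Automated Acoustic Assessment of Speech Dysprosody
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for acoustic assessment of dysprosody
    severity from read-speech recordings. Detects utterance-like vocal
    activity spans, tracks fundamental frequency with a two-pass quartile-
    bounded search, stylizes intonation into Momel target points with INTSINT
    symbolic annotation, extracts a 205-predictor prosodic feature battery
    (timing, f0, intensity, and spectral-tilt measures including SER,
    harmonic level differences with formant correction, C1, and polynomial
    spectral fits), classifies ordinal severity with cross-validation-tuned
    learners and a stacked ensemble, and evaluates predictions against
    ordinal expert ratings with macro one-vs-rest metrics. Includes a
    deterministic synthetic-speech corpus generator so every stage is
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    ranger,
    e1071,
    lhs,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
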