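Package: singrec
Title: Scoring and Modelling of Sung Melodic Recall and Singing Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring sung recalls of melodies and sustained-note
    singing from symbolic note tracks and frame-level pitch tracks, as used in
    online singing ability assessment. Implements the opti3 melodic similarity
    measure (interval n-gram similarity, fuzzified rhythm similarity, and
    implied-harmony similarity via the Krumhansl-Schmuckler key-finding
    algorithm), low-level singing accuracy and precision measures, seven
    sustained-note measures (including dynamic-time-warp distance, a
    Wald-Wolfowitz runs test, and PELT mean-shift changepoint detection),
    melodic feature extraction for explanatory item response modelling,
    n-gram item-bank construction with model-based difficulty prediction,
    signal-to-noise triage and vocal-range transposition, mixed-effects
    ability modelling with Nakagawa-Schielzeth R2, Horn parallel analysis and
    rotated principal-component composites, and a synthetic singer and study
    simulator so every stage is testable without recorded audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
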