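Package: gutwave
Title: Analysis of Gut Mechanosensation from Vibrating-Capsule Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying gut mechanosensation from
    multi-modal physiological recordings collected while participants detect
    vibrations delivered by an ingestible capsule. Provides signal-detection
    scoring of button-press behaviour (A-prime, exact binomial above-chance
    thresholds), extraction of stimulation-locked late positive potentials
    from EEG with threshold-based artifact rejection, a from-scratch
    spatiotemporal cluster-based permutation test, electrogastrogram
    slow-wave spectral and phase analysis with cycle-regularity artifact
    flagging, and cardiac, respiratory and electrodermal quantification
    (tonic and phasic heart rate, SDNN, spectral heart-rate variability,
    autocorrelation breathing-rate estimation, deconvolution-based phasic
    skin conductance). A synthetic multi-rate session generator with known
    ground truth makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
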