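Package: pupildeconv
Title: Online Deconvolution of Task-Evoked Pupillary Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous, causal deconvolution of a pupil-diameter stream into
    latent attentional pulses using an Erlang/gamma impulse-response model of
    the task-evoked pupillary response. Includes the surrounding validation
    pipeline: blink reconstruction, Hampel despiking, gaze/blink trial
    exclusion, event-locked epoching with baseline correction, per-sample
    linear mixed-model significance scanning with a cluster-duration rule,
    pupil feature extraction, cross-validated logistic trial classification
    with ROC/AUC, behavioural indices (Cowan's K, inverse efficiency), and a
    synthetic-data generator with known ground truth so every stage is
    testable without eye-tracking hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    pROC,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
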