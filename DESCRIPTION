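Package: myowrist
Title: Wrist-Position-Independent Myoelectric Hand-Grasp Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying and mitigating the wrist-position effect in
    surface-EMG pattern recognition of hand grasps. Provides a seeded
    synthetic generator of multi-channel EMG sessions with a smooth,
    known dependence of signal statistics on the three wrist angles;
    Chebyshev/Butterworth signal conditioning and sliding-window
    segmentation; the TDAR (time-domain plus sixth-order autoregressive)
    feature set with optional wrist-angle (POS) features; linear and
    quadratic discriminant classifiers and one-hidden-layer perceptrons
    trained by scaled conjugate gradients; a bank of small regression
    networks that predict per-feature mean and variance changes as a
    function of wrist angle relative to a neutral posture; and a data
    simulator that uses those predictions to synthesize multi-position
    training data from neutral-position recordings, enabling
    position-independent classifier training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nnet,
    yaml
Config/testthat/edition: 3
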