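Package: fitfuse
Title: Classifier-Level Fusion of Accelerometer and Surface EMG Signals
    for Fitness Activity Diarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising which fitness exercise is being performed
    from wearable sensing nodes that each record tri-axial acceleration
    (125 Hz) and one surface electromyography channel (2 kHz). Implements
    zero-phase Blackman-Harris FIR preprocessing, segment-adaptive
    overlapping windowing, rotation-vector (axis-angle) features from the
    gravity direction, normalized mean-absolute-value and peak-to-mean
    features from the sEMG envelope, a two-stage classifier-level (stacked)
    fusion of the two modalities, and a leave-two-subjects-out evaluation
    protocol with confusion-matrix aggregation. A seeded synthetic recording
    generator emulates the multi-node, multi-subject structure of upper-arm
    exercise recordings so every stage can be exercised without access to
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    data.table,
    e1071,
    jsonlite,
    rpart,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
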