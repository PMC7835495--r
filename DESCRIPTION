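Package: beechoreo
Title: Head-Thorax Choreography Analysis for Free-Flying Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the coordination of head and thorax movements of
    freely flying insects recorded with marker-based motion capture. Reconstructs
    rigid-body orientation (yaw-pitch-roll) from three-marker sets, smooths pose
    with penalized cubic splines, derives body-frame angular velocity, segments
    flights into saccades and intersaccades with a two-threshold (hysteresis)
    detector, predicts head saccades from windowed thorax angular velocity with
    decision-tree and random-forest classifiers, and maps angular velocity between
    body parts with a small feed-forward network trained under an anti-identity
    loss, including a temporal-shift (forecast/backcast) scan of predictive
    causality. A synthetic flight generator with known ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rpart,
    ranger,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
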