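Package: bipedgait
Title: Gait Event, Momentum and Energetics Analysis for a Planar Spring-Tendon Biped
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing walking experiments on a planar bipedal robot
    with actuated hips and knees and passive, spring-tendon loaded ankles.
    Provides a synthetic sensor-log generator with ground-truth gait-event
    schedules, preprocessing of non-uniformly sampled encoder logs (1000 Hz
    resampling, zero-phase Butterworth filtering, touch-down segmentation and
    ensemble averaging), kinematic detectors for the five gait events around
    push-off, segmental momentum and impulse analysis over the step-to-step
    transition, series-elastic joint power and electrical cost-of-transport
    metrics, and paired Wilcoxon signed-rank comparison of two experimental
    conditions (active versus passive knee-flexion initiation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
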