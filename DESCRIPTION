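Package: imupose
Title: Infant Body-Position Classification from Wearable Inertial Sensors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies infant body position (supine, prone, sitting, upright,
    held by caregiver) from multi-sensor wearable inertial measurement unit
    (IMU) recordings. Implements the full measurement pipeline: reading and
    resampling raw accelerometer/gyroscope streams, impulse-based
    video-to-sensor synchronization, interval-coded annotation handling with
    dual-coder agreement, overlapping 4-s windowing with a 3-of-4-s majority
    labelling rule, a 204-feature motion descriptor set, random-forest
    classifiers in individual (within-infant chronological split) and group
    (leave-one-subject-out) regimes, and a validation toolkit (confusion
    matrices, Cohen's kappa, Landis-Koch interpretation, per-class
    sensitivity/PPV, prevalence correlations, full-day timelines). A seedable
    synthetic IMU session simulator with position-dependent gravity
    orientation and motion dynamics makes every stage testable without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ranger,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'data.R'
    'evaluate.R'
    'features.R'
    'imupose-package.R'
    'methods.R'
    'models.R'
    'pipeline.R'
    'sensor-io.R'
    'synchronize.R'
    'synthetic.R'
    'validation.R'
    'windowing.R'
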