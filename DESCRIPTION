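Package: insoleGait
Title: Gait Type Classification from Smart Insole Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying gait types (walking, fast walking, running,
    stair and hill ascent/descent) from smart-insole recordings that combine a
    quantized plantar-pressure sensor array with acceleration and gyro arrays
    sampled at 100 Hz. Implements rule-based unit-step segmentation anchored on
    the left-foot swing phase, removal of the single-sensor swing-phase noise
    artifact common to insole pressure hardware, resampling of unit steps to a
    common length, and small one-dimensional deep convolutional networks
    (single-modal feature extractors plus a concatenation-fused multi-modal
    classifier) trained by backpropagation with Adam. Includes a synthetic
    recording generator with ground-truth step boundaries, repeated
    random-subsampling and K-fold evaluation protocols, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
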