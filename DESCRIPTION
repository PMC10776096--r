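Package: pennalign
Title: Automatic Ultrasound Probe Alignment for Pennate Muscle Elastography
Version: 0.1.0
Authors@R:
    person("pennalign", "developers", email = "pennalign@example.org",
           role = c("aut", "cre"))
Description: Toolkit for automatic alignment of an ultrasound probe with the
    muscle fiber orientation of pennate muscles during shear-wave elastography
    (SWE). Estimates fiber orientation in B-mode images by adaptive Canny edge
    detection and a probabilistic Hough line transform, locates the SWE
    color-map region of interest on dual-panel scanner screen frames and
    quantifies mean shear-wave velocity with frame- and trial-level quality
    control, and simulates the closed control loop of a stepper-motor driven
    probe rotator (proportional controller, step quantization, smoothed
    velocity profiles, end switches). A seeded synthetic phantom generator
    produces B-mode-like pennate textures, encoded SWE color maps and
    multi-frame trials with known ground truth so the full pipeline is
    testable without a scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    png,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
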