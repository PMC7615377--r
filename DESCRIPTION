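Package: ulmtrack
Title: Acceleration-Based Kalman Tracking for Ultrasound Localisation Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microbubble tracking for super-resolution ultrasound (ultrasound
    localisation microscopy) using a constant-acceleration Kalman motion model
    with a Gaussian-likelihood pairing cost, three-frame motion-state
    initialisation solved by graph assignment, acceleration-based nonlinear
    trajectory interpolation, and rendering of density, velocity and spatial
    speed-gradient maps. Includes a pulsatile microvasculature simulator with
    ground-truth identities and pairing, interpolation and velocity evaluation
    metrics, so the tracker can be exercised and validated end to end on
    synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
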