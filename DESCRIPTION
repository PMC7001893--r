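Package: depthsway
Title: Postural Sway from Depth-Camera Skeletons with Force-Plate Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures upright postural sway from the skeletal joint stream of a
    depth camera and compares it with a force-plate comparator. Implements the
    centre-of-mass (CoM) path pipeline (mediolateral mirroring for a rear-facing
    camera, first-frame alignment, three-joint and segmental CoM estimators),
    the inverted-pendulum projection of centre-of-force to CoM used by
    computerised posturography platforms, resultant-distance and RMS sway
    metrics, and the method-agreement analysis surface (Bland-Altman bias and
    limits of agreement, repeatability coefficients, one-sample and Wilcoxon
    tests, normality screens). A seeded simulator emulates paired recordings
    for the six Sensory Organisation Test conditions so the full pipeline and
    the agreement analysis run without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
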