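Package: stereomid
Title: Synthesis and Analysis of Stereoscopic Motion-in-Depth Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating dynamic random-dot stereogram
    experiments on motion in depth (MID). Generates changing-disparity (CD) and
    interocular-velocity-difference (IOVD) stimulus sequences with matched null
    controls and coherence (signal-to-noise) manipulation; provides cone-contrast
    colorimetry for achromatic and S-cone-isolating dot stimuli including a
    simulated heterochromatic flicker photometry task; implements a Bayesian
    psi adaptive staircase with simulated Weibull 2AFC observers and
    variance-weighted threshold aggregation; supports event-related fMRI design
    generation, gamma HRF convolution, ordinary least-squares fitting of
    synthetic voxel time series, and repeated-measures ANOVA of MID-minus-control
    response differences. All analyses run on synthetic inputs generated by the
    package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
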