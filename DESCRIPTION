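Package: msinrf
Title: Motion Sensing with Intrinsically Nonlinear Receptive Fields
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a spatio-temporal motion sensor built on an
    intrinsically nonlinear receptive field (INRF): a single-neuron model
    whose output combines a linear Gaussian summation term with a
    dendritic-nonlinearity term in which an even, saturating function of
    local luminance differences is shifted by the sensor's own input.
    The package provides the temporal and spatial filters of the model,
    an optimised response engine with an independent brute-force
    reference implementation, a full synthetic-stimulus suite (moving
    bars, drifting and compound gratings, jittering-noise masks, random
    strip patterns, missing-fundamental square waves and
    contrast-modulated second-order stimuli), and scripted experiments
    reproducing six classical motion-perception phenomena: first-order
    motion opponency, contrast saturation, motion masking, reverse-phi,
    the missing-fundamental illusion, and second-order (contrast-defined)
    motion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
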