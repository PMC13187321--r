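Package: wormrig
Title: Virtual Rig and Analysis Pipelines for Closed-Loop Fluorescence
    Imaging of Freely Moving C. elegans
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hardware-free re-creation of a two-channel epifluorescence
    worm-tracking microscope: a virtual rig (simulated undulating worm,
    XYZ stage and dual frame-synced cameras with defocus blur and shot
    noise) drives closed-loop centroid tracking and variance-of-Laplacian
    PID autofocus, and offline pipelines quantify body-wall-muscle,
    sensory-neuron and subcellular axonal calcium signals: midline
    skeletonization with 28-point bend-angle kymographs and dorsal/ventral
    muscle ROIs, brightest-N soma traces with dF/F and signal-to-background
    ratios, ratiometric motion-artifact correction, rotational registration
    of neuron crops with two-compartment segmentation, and phase analysis
    of undulatory locomotion (moving-average smoothing, min/max
    normalization, phase angles, polar binning, cross-correlation,
    gait frequency, event-aligned averaging).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
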