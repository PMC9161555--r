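Package: lightsheetr
Title: Control-Signal Synthesis, Autofocus and Streaming Acquisition for
    Light-Sheet Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-testable computational core of a digital scanned light-sheet
    microscope control platform for whole-brain imaging in larval zebrafish.
    Synthesizes the synchronized per-volume control program (camera trigger
    trains with amplitude-encoded volume boundaries, continuous piezo ramps
    with delay compensation, axial and sheet-forming beam commands, laser
    gates), implements a Fourier-spectrum focus measure with Gaussian
    best-focus fitting and five-point cubic calibration of the scan-axis
    nonlinearity, converts an elliptic eye-exclusion region into per-plane
    laser-off gates, and streams frames from a simulated camera through a
    bounded first-in-first-out buffer into uncompressed HDF5 files under
    zero-loss and bounded-memory contracts. A synthetic nuclear-labeled
    brain phantom and misalignment-dependent blur camera model provide
    ground truth, so every algorithm is testable without microscope
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    rhdf5,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
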