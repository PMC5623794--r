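Package: radiopos
Title: Radiographic Position Recognition and Body-Region Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recognizes the radiographic position (head, lungs, lumbar,
    pelvis, joint, limbs) of a digital radiograph from a one-dimensional
    low-frequency signature of its two-dimensional Fourier spectrum, and
    localizes the imaged body region on an anatomically annotated
    whole-body phantom template by combining a sliding-window
    matrix-product score with a Pearson correlation score. Includes
    radiograph preprocessing (linear histogram stretching, median
    filtering, optional contrast-limited adaptive histogram
    equalization), Butterworth band-pass texture extraction, a synthetic
    whole-body phantom generator for testing and calibration, and a
    command-line interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
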