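Package: thermotex
Title: Ultrasound B-Mode Texture Features for Tissue Thermometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how B-mode ultrasound image texture tracks
    tissue temperature during hyperthermia. Reconstructs 8-bit B-mode
    images from raw radiofrequency (RF) frames (blockwise-max envelope
    detection, log compression, thresholding, median filtering), extracts
    31 texture features from regions of interest (gray-level histogram,
    gray-level co-occurrence matrix at four directions, and gray
    level-gradient co-occurrence matrix statistics), and correlates each
    feature with temperature across a multi-sample heating sweep. A
    synthetic RF generator with a convolutional point-scatterer speckle
    model and a coagulation-plateau echogenicity trend makes the full
    pipeline testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
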