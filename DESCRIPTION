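Package: glomopipe
Title: Glomerulus Detection, Segmentation and Sclerosis Quantification for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step computational pipeline for renal-biopsy whole-slide
    images (WSIs): sliding-window glomerulus detection with duplicate
    bounding-box merging, followed by five-class segmentation of glomerular
    components (background, Bowman's space, glomerular tuft, crescentic
    region, sclerotic region) stitched back into WSI coordinates. Includes
    quantification of sclerotic proportions per glomerulus and per WSI, an
    IoU/F1 evaluation harness with fold aggregation and Welch's t-test, an
    eGFR-slope prognosis regression with standardized coefficients and
    variance inflation factors, and a synthetic phantom-WSI and cohort
    generator so every stage is testable without access to clinical data.
    Detector and segmenter backends are pluggable via simple function
    contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    withr,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
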