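Package: veinline
Title: Finger-Vein Verification with Local Line Binary Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete finger-vein verification pipeline for near-infrared
    finger images: region-of-interest extraction by Otsu thresholding and
    centroid cropping, contrast enhancement with a modified Gaussian
    high-pass filter, translation alignment by phase-only correlation,
    texture coding with the Local Line Binary Pattern (LLBP) family of
    descriptors (horizontal, vertical, concatenated, magnitude) and a
    classic circular LBP baseline, normalized Hamming-distance matching,
    and biometric evaluation (FAR/FRR curves, equal error rate, parameter
    grid search). Includes a deterministic synthetic vein-image generator
    so every stage is testable without access to a capture device.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    png,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
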