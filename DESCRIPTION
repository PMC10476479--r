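Package: maxentseg
Title: Maximum-Entropy Multilevel Thresholding for Grayscale Image
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single- and multi-level gray-image thresholding by histogram
    entropy maximization (Kapur-style criterion), with an exact exhaustive
    oracle and a seeded population-based (genetic) search for the threshold
    vector.  Includes a synthetic abdominal-CT-like liver/tumor phantom
    generator with exact ground truth, segmentation evaluation
    (Dice/Jaccard, confusion matrices, threshold recovery error), image and
    label-map I/O for PNG/TIFF and single-slice NIfTI, and a command-line
    pipeline with reproducibility manifests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    RNifti,
    optparse,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
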