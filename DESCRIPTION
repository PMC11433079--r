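Package: brainlime
Title: Brain-Mask Refinement and Coverage Scoring for Perturbation-Based
    Image Explanations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing and refining perturbation-based local
    explanations (LIME-style heatmaps) of binary tumor classifiers on
    grayscale brain MRI slices. Segments an image into superpixels, fits a
    weighted ridge surrogate over random segment occlusions to obtain
    per-segment importance, extracts a binary brain mask via classical edge
    detectors (Laplacian, Sobel, Canny) or thresholding (Otsu, Li) followed
    by largest-contour filling, and zeroes the importance of any segment
    whose overlap with the brain mask falls below a configurable fraction
    (default 80 percent). Explanation quality is scored with Tumor Segment
    Coverage and Brain Segment Coverage. Includes a synthetic brain-phantom
    generator with ground-truth masks, mock predictors, a VGG Image
    Annotator (VIA) polygon reader, and a batch evaluation harness with
    rank-based statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
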