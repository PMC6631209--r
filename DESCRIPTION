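Package: padcount
Title: Automated Mosquito Counting on Observation-Pad Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for camera-based mosquito surveillance on
    a plain white observation pad. Provides a seeded synthetic scene generator
    with full ground truth (counts, boxes, masks), classical dark-object
    candidate detection (grayscale conversion, thresholding, size-filtered
    contours, 60x60 patch extraction), a patch classifier that bootstraps
    pixel labels for a fully convolutional network, count regression from the
    FCN score map taken before the final deconvolution under a clamped 0-5
    label scheme, a per-contour classification baseline, evaluation metrics,
    and a larvicide-release trigger rule over count time series. Network
    architectures are built both at full scale (for exact parameter-count and
    layer-shape verification) and at reduced width for desk-scale training on
    a CPU.
License: Artistic-2.0
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, EBImage, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
biocViews: Software, Classification, Regression
RoxygenNote: 7.3.3
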