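Package: polypgray
Title: Grayscale Convolutional Detection and Classification of Colorectal Polyps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and optical classification of colorectal polyps in
    endoscopy still frames using lightweight multi-kernel convolutional
    networks operating on grayscale (luma-converted) images. Provides the
    full pipeline: image and annotation input/output (TIFF/PNG, mask or
    bounding-box ground truth), BT.601 luma conversion, an anchor-grid
    single-stage detector with a fully tabulated architecture, a
    neoplastic-versus-hyperplastic texture classifier, the center-point
    (MICCAI endoscopic-vision) evaluation protocol with exact McNemar
    paired tests and Clopper-Pearson intervals, and a seed-deterministic
    synthetic colonoscopy-scene generator so every component is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
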