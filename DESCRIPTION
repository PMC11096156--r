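Package: pearloct
Title: Pearl Luster Grading from OCT B-Scan Speckle Texture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades pearl luster (four classes, A-D) from optical coherence
    tomography (OCT) B-scans of the nacre. Implements automated target
    location (background thresholding, Canny surface detection, polynomial
    flattening, 128x128 subsurface ROI extraction), a bank of seven speckle
    texture descriptor families (fractal dimension by differential box
    counting, gray-level co-occurrence matrices, local binary patterns,
    Gabor filters, histograms of oriented gradients, Laws texture energy,
    and center-symmetric auto-correlation) assembled into a 237-element
    feature vector, and luster classification with support vector machines
    or random forests under randomized hyperparameter search with
    stratified cross-validation, including PCA reduction and backward
    sequential feature selection. A synthetic B-scan generator with
    class-dependent correlated speckle makes the full pipeline testable
    without proprietary pearl images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    randomForest,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
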