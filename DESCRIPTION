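Package: echocalc
Title: Semi-Automatic Calcium Identification and Quantification from Echocardiographic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies aortic-valve calcium on still grayscale
    echocardiographic images by adaptive binarization. A fixed intensity
    threshold is shifted per image by the mean of a user-selected dark
    blood-pool region (the "black threshold"), after optional compensation of
    post-processing display gains estimated from a region outside the
    ultrasound sector. White pixels inside a valve region of interest are
    counted as a proxy of calcium area, and raw and dark-normalized intensity
    statistics are reported. Includes a synthetic sector phantom generator
    with exact ground truth for validating every stage, and the agreement
    statistics (population standard deviation across acquisitions, Pearson
    correlation against expert planimetry) used to evaluate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    grDevices,
    graphics,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
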