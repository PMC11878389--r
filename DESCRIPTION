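Package: topotype
Title: Simulation and Neural Classification of Corneal Topography Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for keratoconus screening research on color-coded corneal
    topography maps. Simulates labelled axial-power topograms of the four
    diagnostic patterns (spherical, regular symmetric astigmatism, regular
    asymmetric astigmatism, irregular astigmatism / keratoconus) together
    with perspective-distorted captures; rectifies captures into a canonical
    3/5/7-mm zone frame via a four-point homography and converts them to HSV;
    derives examiner-style iso-power contours with geometric bow-tie
    descriptors and a rule-based reference classifier; trains a small
    convolutional network with paired convolution/max-pooling layers on the
    contour masks; and computes confusion-matrix screening statistics
    (sensitivity, specificity, per-class error rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
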