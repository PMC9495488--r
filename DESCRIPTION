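Package: ecgmi
Title: Image-Based Myocardial Infarction Detection and Localization from
    12-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 12-lead electrocardiogram records into sets of twelve
    64x64 grayscale images by non-overlapping window shifting and antialiased
    polyline rasterization, classifies the image sets with a 12-branch
    convolutional neural network (one convolution/pooling tower per lead,
    late feature fusion, batch normalization, softmax head, Adam training),
    and evaluates myocardial-infarction detection and infarct-site
    localization under both random ten-fold and subject-held-out
    cross-validation with sensitivity, specificity and accuracy reporting.
    Includes a seeded synthetic 12-lead ECG generator with class-specific,
    lead-localized infarction morphology so the full pipeline is testable
    without access to clinical data, plus WFDB and CSV record I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
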