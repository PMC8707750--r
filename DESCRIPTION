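Package: gazeits
Title: Imaging Time Series and Heterogeneous CNN Classification of Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies internally versus externally directed attention from
    binocular eye-tracking recordings. Converts gaze and pupil time series
    into explicit statistical descriptors (fixations via dispersion-threshold
    identification, saccades, blinks, vergence and pupillometric summary
    statistics) and into implicit image representations (Markov transition
    fields and Gramian angular summation/difference fields), and classifies
    trials with a two-branch convolutional neural network that optionally
    fuses the explicit feature vector mid-network. Includes a synthetic
    binocular gaze generator with controllable class structure, person-dependent,
    person-independent and task-independent evaluation protocols, exact binomial
    better-than-chance thresholds, and Benjamini-Hochberg multiple-testing
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
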