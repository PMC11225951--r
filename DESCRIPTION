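Package: ocdci
Title: Online Changepoint Detection with Confidence Intervals and Support
    Recovery in High Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequential detection of a sparse mean change in a
    high-dimensional data stream, with post-declaration inference. Implements
    the ocd family of online detectors based on residual tail lengths and
    multiscale likelihood-ratio statistics, Monte-Carlo calibration of the
    declaration thresholds to a target patience, a confidence interval for
    the changepoint location built from shrunken per-coordinate scale
    estimates, and an estimate of the set of coordinates undergoing the mean
    change. Includes a synthetic stream simulator, a simulation harness for
    coverage, interval-length, delay and support-recovery studies, and a
    preprocessing pipeline that turns weekly regional death-count panels into
    standardized excess-death streams for surveillance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
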