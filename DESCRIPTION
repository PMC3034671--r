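Package: platescan
Title: Systematic Error Detection and Correction for High-Throughput
    Screening Plate Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of high-throughput screening (HTS)
    microtiter-plate assays. Detects positional (row, column and well)
    systematic error with a pooled-variance t-test scan, a chi-squared
    goodness-of-fit test on hit-distribution surfaces, and a discrete
    Fourier transform power-spectrum procedure followed by a
    Kolmogorov-Smirnov check. Provides the standard plate normalizations
    (percent of control, normalized percent inhibition, Z-score, B-score
    via two-way median polish, and well correction), hit selection at
    mean-minus-c-sigma thresholds, hit-distribution surfaces, replicate
    combination, and a simulation harness that generates assays with five
    positional error models and scores detector output against ground
    truth with Cohen's kappa, sensitivity, specificity and success rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
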