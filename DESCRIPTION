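Package: shiftmatch
Title: Probabilistic Cross-Peak Matching Between Multidimensional NMR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Matches cross-peaks between a reference and a target
    multidimensional NMR peak list and reports calibrated posterior match
    probabilities, including an explicit no-match outcome. Uncertainty
    normalised squared distances between peaks are modelled with a
    hierarchical mixture of a chi-squared noise component, a heavy-tailed
    Frechet component for genuine chemical shift perturbations (CSPs), and
    a uniform pseudo-likelihood for non-matching pairs. Complete matching
    matrices are sampled under one-to-one exclusivity constraints with a
    sequential Monte Carlo sampler using beam-search proposals, stratified
    resampling and adaptive sample sizes; mixture parameters are fitted by
    expectation-maximization. Includes readers for Sparky/POKY peak lists,
    a synthetic peak-list simulator with ground truth, CSP detection and
    estimation utilities, evaluation against ground truth, and a small
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
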