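Package: mcsampen
Title: Exact and Monte Carlo Sample Entropy for Long Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sample entropy (SampEn) quantifies the irregularity of a
    univariate time series as -log(B/A), where A and B count template
    pairs of lengths m and m+1 that match within a Chebyshev tolerance r.
    Direct computation costs O(N^2) and becomes prohibitive for long
    physiological recordings. This package provides the exact estimator
    by direct range counting together with MCSampEn, a Monte Carlo
    estimator that repeatedly subsamples N0 template indices uniformly
    without replacement (via the Hidden Shuffle sequential sampler),
    averages the subsample pair counts over N1 experiments, and returns
    -log(Bbar/Abar) at a cost independent of the series length. The
    closed-form expectation and variance of the subsample pair-count
    estimators are implemented along with exhaustive-enumeration
    verification tools, MIX(p) and 1/f-noise benchmark generators, and a
    repeated-run error-evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
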