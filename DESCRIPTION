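Package: dynmod
Title: Dynamic Modular Architecture of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window construction of fully connected, signed, weighted
    connectivity graphs from ROI-level brain time series, community detection
    and modularity scoring (Q*) on signed graphs with strength-preserving null
    models, data-driven window-length selection, modular and sub-network
    dwell-time statistics, meta-modular consensus clustering, and two-group
    comparison of dwell times. Includes a synthetic generator of switching-state
    multivariate BOLD-like signals with known modular ground truth for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
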