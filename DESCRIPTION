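Package: rhythmeb
Title: Effect-Size Quantification of Rhythmicity in Genomic Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rhythmicity in genomic time-series data (e.g. circadian
    transcriptomes) by effect size rather than statistical significance. Fits
    each feature with a series of knot-shifted periodic cubic-spline (or
    cosinor) linear models, moderates the time coefficients across features
    with an empirical-Bayes multivariate adaptive shrinkage prior (a mixture of
    multivariate normals fitted by EM), and reports rhythm statistics (mesor,
    peak, trough, peak-to-trough and RMS amplitude, peak and trough phase) with
    posterior credible intervals obtained from posterior draws, including a
    sign-flip rule that lets amplitude intervals of weak rhythms span zero.
    Includes raw-count preprocessing (CPM filtering, zero-count imputation,
    log2-CPM transform), a synthetic-data generator with known rhythm
    parameters, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    splines,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
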