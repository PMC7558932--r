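Package: hrvbayes
Title: Heart Rate Variability Indices and Bayesian Correlation Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for short-term heart rate variability (HRV) analysis and
    Bayesian correlation estimation. Reads plain-text inter-beat-interval
    (IBI) recordings, flags isolated artifacts with a quartile-trimmed
    threshold rule, and computes time-domain (MeanRR, SDNN, RMSSD, pNN50),
    frequency-domain (smoothness-priors detrending, Welch band power in the
    LF and HF bands with normalized units) and Poincare (SD1, SD2) indices.
    Pairwise associations between HRV indices, blood-pressure indices and
    aerobic-capacity measures are estimated with a native component-wise
    Metropolis sampler for the bivariate normal correlation model, reported
    as posterior medians with 95% highest-density intervals, convergence
    diagnostics (PSRF, effective sample size, Monte Carlo standard error)
    and posterior predictive ellipse checks. A synthetic-data module
    generates tachograms, artifact injections and correlated samples with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    e1071
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
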