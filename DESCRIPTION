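Package: pulsedecon
Title: Sparse Deconvolution of Pulsatile Hormone Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the number, timing and amplitude of sparse hormone
    secretory events, together with the infusion and clearance rates of a
    two-compartment kinetic model, from coarsely sampled serum concentration
    time series (e.g. 24-hour cortisol profiles sampled every 10 minutes).
    Estimation alternates nonnegative sparse recovery by the FOCUSS+
    reweighted-norm algorithm, with the regularization parameter selected at
    each iteration by generalized cross-validation, and constrained nonlinear
    least-squares fitting of the kinetic parameters. Includes a synthetic-data
    generator for pulsatile profiles with gamma interarrival times and
    circadian-modulated amplitudes, recovery-quality metrics, and tidy and
    ggplot2 methods for the fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    knitr,
    optparse,
    patchwork,
    pracma,
    testthat (>= 3.0.0),
    rmarkdown,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
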