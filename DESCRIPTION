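Package: grnabc
Title: Surrogate-Accelerated ABC Inference Evaluation for Negative-Feedback
    Gene Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to systematically evaluate likelihood-free (approximate
    Bayesian computation, ABC) parameter inference for a canonical
    negative-feedback gene regulatory network simulated at three levels of
    fidelity: a well-mixed Gillespie model, a two-compartment multiscale
    model with first-passage derived nucleus/cytoplasm transfer rates, and
    a Brownian-dynamics particle model in the Smoluchowski spirit.
    Ground-truth trajectory ensembles are generated on a known-truth
    parameter grid, Gaussian-process surrogates emulate distance-metric
    values over (log D, log chi) so that full ABC-SMC sweeps need no
    further simulation, and inference accuracy is summarised as expected
    log-error maps and extended (boxen) quantile summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    withr,
    MASS,
    stats,
    utils,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
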