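Package: mnarhmm
Title: Hidden Markov Models with State-Dependent Missingness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits inhomogeneous Gaussian hidden Markov models to longitudinal
    data in which the response may be missing not at random (MNAR), with the
    probability of a missing observation depending on the hidden state and on
    covariates through per-state logistic regressions. Provides scaled
    forward-backward smoothing and Viterbi decoding under ignorable (MAR) and
    state-dependent MNAR observation channels, Baum-Welch EM estimation with
    weighted generalized-linear M-steps and multistart, model diagnostics
    (likelihood-ratio test of the MAR restriction, information criteria,
    pseudo-residuals, finite-difference standard errors), and a simulation
    framework emulating clinical-trial dropout for benchmarking MAR against
    MNAR models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
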