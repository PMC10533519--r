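Package: iatdyn
Title: Time-Evolving Ex-Gaussian Modeling of Implicit Association Test
    Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing within-session dynamics of Implicit
    Association Test (IAT) response times. Response times are modeled as
    ex-Gaussian, with the mean of the exponential component following a
    three-parameter saturating trajectory over trials (starting level,
    time constant in trials, asymptotic level) embedded in a hierarchical
    fixed/random-effects structure with log links. Includes conventional
    improved D-scoring with the field's trial and participant filters,
    an empirically determined lower response-time cutoff, block-level
    contrasts with bootstrap effect-size intervals, cross-validated
    comparison against a static null model, participant-level trajectory
    indices, robust Mahalanobis outlier rejection, bootstrapped robust
    regression linking indices to external behavioral measures, and a
    synthetic-data generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    jsonlite,
    pracma,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
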