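Package: punishr
Title: Bayesian Phylogenetic Analysis of Cross-Cultural Punishment Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analyses of punishment systems across
    societies: descriptive statistics over society-by-(norm violation,
    punishment type) evidence codings, multiple imputation of missing
    socioecological predictors by chained equations, and a multi-response
    Bayesian phylogenetic logistic regression of punishment-type evidence on
    socioecological predictors with per-outcome phylogenetic random effects,
    correlated society-level effects, latent-scale phylogenetic-signal
    estimation, and posterior summaries (highest-posterior-density intervals,
    probability of direction, evidence classification). Includes a synthetic
    study generator with known ground truth for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    coda,
    Matrix,
    jsonlite,
    MASS,
    stats,
    TMB,
    utils,
    yaml
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
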