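Package: hsanet
Title: Weighted Hospital Service Area Networks and Multiple-Membership
    Multilevel Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-flow-weighted hospital catchments
    (weighted hospital service area networks) and discrete plurality-rule
    hospital service areas from admission records, fits multilevel Poisson
    models with single-membership, multiple-membership and cross-classified
    random classifications by MCMC (adaptive Metropolis-within-Gibbs), and
    summarises between-hospital variation as median rate ratios, proportional
    changes in variance, DIC and posterior hospital rankings. Includes a
    synthetic patient-flow generator with known ground truth so the full
    pipeline can be exercised without confidential linked data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp,
    coda,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
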