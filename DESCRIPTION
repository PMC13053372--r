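Package: cmsem
Title: Composite Moderated Structural Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of moderated mediation models in which a construct is an
    unknown-weight composite (emergent variable). Implements the three-step CMS
    estimator: a confirmatory composite/factor analysis using the refined
    Henseler-Ogasawara specification with a banded composite-loading pattern,
    extraction of composite weights by inversion of the estimated loading matrix,
    and full-information maximum likelihood estimation of the latent interaction
    model by numerical integration of the marginal likelihood (latent moderated
    structural equations). Includes a population model generator and a Monte
    Carlo driver for evaluating bias, variance, mean squared error, power of the
    moderation test, and the share of inadmissible solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
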