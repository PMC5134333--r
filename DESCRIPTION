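Package: hillbayes
Title: Bayesian and Hierarchical Bayesian Inference for Hill Dose-Response Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Hill (concentration-effect) curves to ion-channel screening
    data in a Bayesian framework, returning posterior distributions for pIC50,
    Hill coefficient and observation noise rather than point estimates. Supports
    a pooled single-level model and a hierarchical model in which each
    experimental repeat has its own pIC50 and Hill coefficient drawn from
    logistic and log-logistic population distributions with gamma hyperpriors.
    Inference uses covariance matrix adaptation evolution strategy (CMA-ES)
    optimisation to locate a starting point followed by adaptive
    Metropolis-Hastings MCMC with a truncated-normal observation likelihood.
    Includes posterior-predictive distributions with inverse-CDF sampling,
    percent-block prediction at arbitrary concentrations, a synthetic
    dose-response data generator, CSV input/output in a simple record format,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
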