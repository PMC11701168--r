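Package: abxasthma
Title: Counterfactual Impact of Infant Antibiotic Exposure on Pediatric
    Asthma Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counterfactual impact analysis of infant antibiotic
    exposure on the population burden of pediatric asthma. Implements
    negative binomial trend modelling of annual infant antibiotic
    prescription rates with a stewardship-program breakpoint, Bayesian
    random-effects dose-response meta-regression of antibiotic exposure
    and childhood asthma on the logit scale, an open-population
    discrete-time asthma microsimulation (onset, remission,
    exacerbations) with common-random-number scenario pairing, and
    excess-burden reporting with age-group decomposition and direct
    medical cost translation. A synthetic-data module generates all
    pipeline inputs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    rjags,
    coda,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
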