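Package: obdsub
Title: Subgroup-Specific Optimal Biological Dose Finding with
    Spike-and-Slab Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian adaptive phase I/II dose-finding for trials with two
    prespecified patient subgroups in which the optimal biological dose
    (OBD) may differ between subgroups.  Implements quadratic dose-efficacy
    and linear dose-toxicity Bernoulli-logit models with spike-and-slab
    priors on the subgroup effects, Polya-Gamma Gibbs sampling, prior
    calibration to elicited outcome probabilities and a target effective
    sample size, utility-based dose assignment with posterior admissibility
    rules, a rule-based run-in, and a simulation harness that compares the
    subgroup-aware design against pooled and independent dose-finding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    parallel,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
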