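Package: betacog
Title: Bayesian Hierarchical Beta Regression for Bounded Longitudinal
    Cognitive Test Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bounded, skewed neuropsychological test
    scores (such as the 0-37 Blessed Information-Memory-Concentration
    test) collected longitudinally in very old cohorts.  Scores are
    rescaled to the open unit interval and modelled with a hierarchical
    beta regression with a logit link, a precision parameter, and a
    piecewise random intercept that accommodates participants with a
    single assessment alongside participants with repeated assessments.
    Includes an adaptive Metropolis-within-Gibbs sampler, deviance
    information criterion (DIC) backward model selection with
    credible-interval refinement, prior-sensitivity refits, marginal
    fitted-trajectory and onset-of-impairment summaries, a Gaussian
    random-intercept linear mixed model comparator, and a synthetic
    cohort generator emulating a centenarian cohort with APOE genotypes,
    education, and injectable missingness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    lme4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
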