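# betacog

Bayesian hierarchical beta regression for bounded, skewed
neuropsychological test scores collected longitudinally in cohorts of the
very old, with APOE allele group, education, age and sex as covariates.

## Why

Global cognition screens such as the Blessed
Information-Memory-Concentration (BIMC) test are scored on a bounded scale
(0–37; 21–26 indicates moderate impairment).  In centenarian cohorts the
scores are skewed and pile up near the boundaries, so the conventional
Gaussian random-intercept linear mixed model can predict impossible scores
(above the ceiling) and misfit the accelerating decline.  `betacog`
rescales scores onto $[0.01, 0.99]$ via $y' = 0.01 + 0.98\,y/37$ and
models them as

$$y'_{ij} \sim \mathrm{Beta}(\mu_{ij}\phi,\ (1-\mu_{ij})\phi), \qquad
\mathrm{logit}(\mu_{ij}) = \mu_b I_i + b_i(1 - I_i) + x_{ij}^\top\beta ,$$

with variance $\mu(1-\mu)/(1+\phi)$, standardized covariates in $x_{ij}$
(age, age², sex, education, APOE allele-group dummies with e3e3 as
reference, and two-way interactions), and a *piecewise* random intercept:
participants with a single assessment ($I_i = 1$) get the population mean
$\mu_b$, participants with repeats get $b_i \sim N(\mu_b, \sigma_b^2)$.
Priors are $N(0, 1000)$ on location parameters and Gamma(1, 1) on $\phi$
and on $1/\sigma_b^2$.  Fitting is by an adaptive Metropolis-within-Gibbs
sampler (Rcpp); model choice is backward DIC search refined by 95%
credible intervals; results are summarized as fitted 0–37 trajectories
with credible bands and ages of onset of moderate impairment (score = 26).
A matching `lme4` linear-mixed-model comparator, with parametric-bootstrap
bands, quantifies what the beta model buys (in-range fitted values, lower
RSS).

Because the motivating cohort data are access-restricted, the package
ships a synthetic cohort generator emulating that study's structure
(genotype quotas 117/331/38 across e2/e3/e4 groups plus 4 e2e4 carriers in
the complete-data subset of 768 genotyped participants, ages 91–113,
education quartiles 8/12/15, 49% single-assessment participants, 167
missing-score and 111 missing-education participants), so every stage is
testable against known truth.

## Worked example

```r
library(betacog)

cohort <- generate_cohort(default_cohort_config(seed = 7))
excl   <- apply_exclusions(cohort)
excl$log
#>              reason n_excluded
#> 1     missing_score        167
#> 2 missing_education        111
#> 3     genotype_e2e4          4
excl$n_retained
#> [1] 486

aset <- make_analysis_set(cohort, "e2_vs_e3")
fit  <- fit_beta_model(aset, c("age", "sex", "edu", "apoe", "edu_apoe"),
                       config = mcmc_config(n_chains = 3, seed = 11))
fit
#> Hierarchical beta regression fit
#> Terms: age, sex, edu, apoe, edu_apoe
#> DIC: -561.79 (pD = 90.11)
#>   parameter   mean     sd   lower median   upper
#> 1       age -0.147 0.0323 -0.2121 -0.148 -0.0846
#> 2       sex  0.208 0.0775  0.0577  0.208  0.3620
#> 3       edu  0.126 0.0384  0.0476  0.126  0.2001
#> 4     apoe2 -0.030 0.0736 -0.1803 -0.029  0.1153
#> 5 edu_apoe2 -0.150 0.0711 -0.2875 -0.152 -0.0102
#> 6      mu_b  0.653 0.0431  0.5647  0.655  0.7358
#> 7       phi  5.127 0.2379  4.6793  5.120  5.5989
#> 8  sigma2_b  0.128 0.0266  0.0823  0.125  0.1852
```

The cohort was generated with a negative age effect, positive male-sex and
education effects, and a negative education-by-e2 interaction (the default
`true_params`); the posterior recovers each of them within its credible
interval.  `phi` near 5 says a participant's conditional score variance is
$\mu(1-\mu)/6$ on the unit scale; `sigma2_b` is the between-participant
intercept variance on the logit scale.  Onset ages and trajectories then
come from the posterior:

```r
prof  <- covariate_profile(sex = "female", education_years = 8,
                           allele_group = "e3")
pm    <- colMeans(combine_chains(fit$samples))
onset_age(pm[c("age","sex","edu","apoe2","edu_apoe2","mu_b")],
          prof, aset$scaling)   # age where the fitted curve crosses 26
#>        age  direction
#> 1 95.68486 descending
band <- fitted_band(fit$samples, prof, seq(91, 113, 0.5), aset$scaling)
range(band$lower, band$upper)   # always inside [0, 37]
#> [1] 19.07838 28.81482
```

The numbered scripts under `analysis/` run the full workflow (simulate →
preprocess → fit → select → effects → LMM comparison) and write tables
under `results/`.

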