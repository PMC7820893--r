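---
title: "Modelling bounded cognitive test scores with hierarchical beta regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bounded cognitive test scores with hierarchical beta regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Global cognition screens such as the Blessed Information-Memory-Concentration
(BIMC) test are scored on a bounded scale (0--37, higher is better; scores of
21--26 indicate moderate impairment).  In very old cohorts the score
distribution is strongly skewed and piles up near the boundaries, so the
Gaussian linear mixed model that is conventionally used for longitudinal
neuropsychological data can fit poorly near the floor and ceiling and can
predict impossible scores.  `betacog` instead models the score with a beta
distribution, which respects the bounds by construction, and is aimed at
longitudinal cohorts of the very old (ages 91--113) in which age, sex,
education and APOE allele group are the covariates of interest.

## The model

Scores are first mapped affinely from $[0, 37]$ onto $[0.01, 0.99]$,
$y' = 0.01 + 0.98\,y/37$, so that the boundary scores stay inside the open
support of the beta distribution.  In the mean--precision parameterization,
$y' \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ has mean $\mu$ and variance
$\mu(1-\mu)/(1+\phi)$; $\phi > 0$ is a precision parameter.  The mean of
observation $j$ of participant $i$ follows

$$\mathrm{logit}(\mu_{ij}) = \mu_b I_i + b_{i}(1 - I_i) + x_{ij}^\top\beta,$$

where $x_{ij}$ collects standardized age, age$^2$, sex (0 = female,
1 = male), standardized education, allele-group dummies (e3e3 homozygotes
are the reference; e2 = \{e2e2, e2e3\}; e4 = \{e3e4, e4e4\}; e2e4 carriers
are excluded as unclassifiable) and two-way interactions.  The intercept is
*piecewise*: participants with a single assessment ($I_i = 1$) receive the
population mean $\mu_b$, while participants with repeated assessments draw
their own intercept $b_i \sim N(\mu_b, \sigma_b^2)$.  This keeps
single-assessment participants (about half of a cohort at these ages, due
to mortality) in the likelihood without pretending their intercept is
identified.

Priors are weakly informative: $N(0, 1000)$ on $\mu_b$ and on every fixed
effect, and $\mathrm{Gamma}(\text{shape}=1, \text{scale}=1)$ — i.e.
Exponential(1) — on $\phi$ and on the random-intercept precision
$1/\sigma_b^2$.  The prior-sensitivity utility refits under normal
variances 10 and 100 and a gamma variance of 100 (shape 1, scale 10); on
well-identified data the fixed-effect posterior means move by well under
half a posterior standard deviation (the variance components' posteriors
naturally track their own prior scales more closely).

## Preprocessing conventions

* Exclusions run in a fixed order — participants with no observed score,
  then participants with missing education, then e2e4 carriers — and are
  logged per reason; the operation is idempotent.
* Age is standardized over all retained test administrations (age is
  time-varying); education over participants (one value each).  The
  constants are stored with every analysis set so fitted curves can always
  be mapped back to raw years.  Row-level and participant-level
  standardization of age differ slightly and published onset ages are
  sensitive to this choice, which is why onset ages are treated as
  qualitative orderings rather than exact targets.
* `age2` is the square of standardized age, keeping the age and curvature
  coefficients on comparable scales and making threshold inversion a
  quadratic problem.
* Terms obey marginality: an interaction (or `age2`) is only ever included
  together with its parent main effects.

## Sampler

The posterior is explored with an adaptive Metropolis-within-Gibbs sampler
written in C++ (Rcpp): scalar Gaussian random-walk updates for each fixed
effect, $\mu_b$, each non-singleton $b_i$, $\log\phi$ and
$\log\sigma_b^2$ (the log transforms carry their Jacobians; the gamma
prior is placed on the precision $1/\sigma_b^2$ exactly as specified
above).  Proposal scales adapt by Robbins--Monro toward 35% acceptance
during burn-in only, so the retained chain has the correct stationary
distribution.  Defaults are 3 chains of 8000 burn-in plus 4000 retained
iterations.  Initialization is deterministic and data-informed: fixed
effects at 0, $\mu_b$ at the logit of the mean rescaled score, $\phi$ at
its method-of-moments estimate, $b_i$ at $\mu_b$, $\sigma_b^2$ at 0.25.
Chain $c$ is seeded with `seed + c - 1`, making every fit exactly
reproducible.  Convergence is checked with split-chain Gelman--Rubin
$\hat R$ and sample autocorrelations; one test cross-checks the sampler's
posterior means against an independent Gibbs engine (JAGS) on the same
small dataset.

## Model selection

Backward search starts from the full model (all main effects, `age2`, all
two-way interactions) and at each step drops the droppable term whose
removal most decreases the conditional DIC
($\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, with the
random intercepts plugged into the plug-in deviance), stopping when no
removal helps.  Candidate fits within a step share one seed so DIC
differences are not dominated by seed noise; ties break toward
higher-order terms, then alphabetically.  Because DIC tends to overfit,
the selected model is then pruned: a term survives only if the equal-tailed
95% credible interval of at least one of its coefficients excludes 0,
except that a main effect is always retained while a surviving interaction
contains it (this is exactly the pattern in which a main APOE effect whose
CI spans zero stays in the model because its education interaction does
not).  The pruned model is refit once.

## Effect summaries

Marginal fitted scores use $\mu_b$ as the intercept (a population-typical
participant rather than an average over posterior $b_i$ draws), invert the
logit and map back to the 0--37 scale; means falling in the 1% rescaling
guard bands are mapped to the boundary scores, so fitted values and their
credible bands lie in $[0, 37]$ *by construction* — the property the
Gaussian comparator lacks.  Education profiles default to the 8 / 12 / 15
year quartiles with sex = female.  The onset of moderate impairment is the
age at which a fitted trajectory crosses score 26, found by bisection to
far below 0.01 years within the observed 91--113 range; with a curvature
term both crossings are reported and the descending one flagged as
clinically relevant; never-crossing trajectories report which side of the
threshold they stay on.  Fit quality is summarized by the residual sum of
squares of the conditional per-row fitted values and by explained variance
(regression sum of squares over total sum of squares).

## The Gaussian comparator

`fit_lmm()` fits the same terms to the raw 0--37 scores with a
random-intercept Gaussian model via `lme4::lmer`.  Estimation is ML rather
than REML so likelihoods remain comparable across mean structures; the
difference is immaterial for the comparison being made.  Wald $t$ and $p$
values use the normal approximation.  Confidence bands for fitted values
come from a parametric bootstrap (simulate from the fitted model, refit,
recompute; 1000 replicates by default).  When no participant has repeated
measurements the random intercept is unidentifiable and the fit collapses
to OLS with $\sigma_b^2$ pinned at 0 (with a warning).

## The synthetic cohort generator

No public version of the motivating dataset exists (its use is
restricted), so the package ships a generator whose defaults emulate the
study's margins: 768 genotyped participants; genotype quotas whose
complete-data subset reproduces 117 / 331 / 38 participants in the
e2 / e3 / e4 groups plus 4 e2e4 carriers; enrollment ages
$N(103.3, 4.5^2)$ truncated to 91--113; a discrete education distribution
with quartiles 8 / 12 / 15 (mean ≈ 11.5); 24% male; 49% of participants
with only the baseline assessment and a geometric tail of 2--8 annual
follow-ups truncated at age 113; 167 participants with missing scores and
111 with missing education.  Genotypes are assigned by largest-remainder
quota rather than i.i.d. draws so that cohort accounting — in particular
the rare e2e4 count that drives an exclusion — is reproducible, and the two
missingness subsets are drawn disjointly from non-e2e4 participants,
mirroring sequential exclusion accounting (768 − 167 − 111 − 4 = 486).

Outcomes are drawn from the model above with true parameters defaulting to
the fitted-model shape: $\mu_b = 0.592$, $\beta_{age} = -0.110$,
$\beta_{sex} = 0.262$, $\beta_{edu} = 0.062$, $\beta_{APOE2} = 0.037$,
$\beta_{edu \times APOE2} = -0.063$ (and the analogous e4 effects
$-0.382$ / $-0.082$), with $\phi = 5$ and $\sigma_b = 0.35$ chosen once so
the marginal score standard deviation is about 8 points — the scale seen
in such cohorts.  Continuous beta draws are mapped to integer scores by
inverting the rescaling and rounding (how integer scores arise from the
continuous model is unstated in the field; rounding is the natural
choice).  Each participant has its own RNG stream, which makes cohorts
reproducible under partial regeneration; the stream seeds are themselves
drawn from the master stream rather than taken as consecutive integers,
because consecutively seeded Mersenne-Twister states are under-mixed and
their early draws correlate across streams — enough, at these sample
sizes, to induce a spurious education-age correlation and bias the
recovered education coefficient.

What the generator does *not* emulate: informative dropout and mortality
(the singleton fraction is a knob, not a survival process), practice
effects, proxy-administration effects, cohort trends in education, and the
integer measurement process beyond rounding.  Passing recovery tests on
these cohorts therefore shows the estimator is correct under the stated
model, not that the model is correct for any real cohort.

## Numerical choices and problem sizes

Test and example problem sizes are chosen for fast, deterministic runs:
unit tests use cohorts of 40--200 participants with short chains
(1--2 chains, a few hundred to a few thousand iterations); the
parameter-recovery study uses 20 replicate cohorts of 480 participants fit
at the default run lengths; the selection check compares
backward search against exhaustive enumeration on a 3-term candidate set,
where both are feasible.  Posterior credible intervals are equal-tailed;
quantiles use the default type-7 estimator.  Degenerate inputs are
rejected loudly (constant vectors in standardization, boundary values in
the beta density, singular LMM designs) rather than silently patched.

## Known limitations

The sampler is random-walk Metropolis, adequate at these dimensions
(tens of fixed effects plus a few hundred intercepts) but not competitive
with gradient-based samplers for much larger problems.  DIC is the
selection criterion by design; WAIC/LOO are not implemented.  Onset ages
inherit the standardization conventions above and should be compared
across profiles, not read as calendar-age point predictions.  The
education-by-APOE interaction is an observational association; nothing
here supports a causal reading.
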