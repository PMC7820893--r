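# Shared fixtures: small synthetic cohorts, designs, and an independently
# coded log-posterior oracle.

# A small, fast cohort restricted to e2/e3 genotypes with no missingness.
small_e2e3_config <- function(n = 120, seed = 1, true = NULL) {
  cohort_config(
    n_participants = n,
    genotype_probs = c(e2e2 = 0.02, e2e3 = 0.22, e3e3 = 0.76,
                       e3e4 = 0, e4e4 = 0, e2e4 = 0),
    true_params = if (is.null(true)) default_true_params() else true,
    seed = seed
  )
}

small_aset <- function(n = 120, seed = 1, true = NULL,
                       contrast = "e2_vs_e3") {
  make_analysis_set(generate_cohort(small_e2e3_config(n, seed, true)),
                    contrast)
}

# Short MCMC settings for unit tests.
quick_mcmc <- function(seed = 1, n_chains = 2, n_burn = 1200, n_iter = 800) {
  mcmc_config(n_chains = n_chains, n_burn = n_burn, n_iter = n_iter,
              seed = seed)
}

# A random small model_design, for likelihood-level oracles.
random_design <- function(n_participants = 5, p = 2, seed = 1) {
  set.seed(seed)
  n_obs <- sample(1:3, n_participants, replace = TRUE)
  participant <- rep(seq_len(n_participants), n_obs)
  n <- length(participant)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, if (p > 0) paste0("x", seq_len(p))))
  structure(list(
    X = X,
    y = runif(n, 0.05, 0.95),
    participant = participant,
    singleton = as.numeric(n_obs == 1),
    term_of_column = setNames(colnames(X), colnames(X)),
    terms = character(0), contrast = "e2_vs_e3",
    scaling = list(age_mean = 103, age_sd = 4, edu_mean = 12, edu_sd = 4)
  ), class = "model_design")
}

random_params <- function(design, seed = 1) {
  set.seed(seed)
  list(beta = rnorm(ncol(design$X), 0, 0.5),
       mu_b = rnorm(1, 0, 0.5),
       b = rnorm(length(design$singleton), 0, 0.5),
       phi = runif(1, 2, 20),
       sigma2_b = runif(1, 0.05, 1))
}

# Independent term-by-term recomputation of the joint log posterior, written
# against the model definition rather than the package internals.
oracle_log_posterior <- function(params, design, priors) {
  total <- 0
  for (i in seq_along(design$y)) {
    pid <- design$participant[i]
    icpt <- if (design$singleton[pid] == 1) params$mu_b else params$b[pid]
    eta <- icpt
    for (k in seq_len(ncol(design$X))) eta <- eta + design$X[i, k] * params$beta[k]
    mu <- 1 / (1 + exp(-eta))
    total <- total + dbeta(design$y[i], mu * params$phi,
                           (1 - mu) * params$phi, log = TRUE)
  }
  for (pid in seq_along(design$singleton)) {
    if (design$singleton[pid] == 0)
      total <- total + dnorm(params$b[pid], params$mu_b,
                             sqrt(params$sigma2_b), log = TRUE)
  }
  for (k in seq_along(params$beta))
    total <- total + dnorm(params$beta[k], 0, sqrt(priors$beta_var), log = TRUE)
  total <- total + dnorm(params$mu_b, 0, sqrt(priors$mu_b_var), log = TRUE)
  total <- total + dgamma(params$phi, shape = priors$phi_shape,
                          scale = priors$phi_scale, log = TRUE)
  tau <- 1 / params$sigma2_b
  total + dgamma(tau, shape = priors$tau_shape, scale = priors$tau_scale,
                 log = TRUE) + 2 * log(tau)
}

# Assemble a posterior_samples object from a single draw matrix, for tests
# that need posteriors with prescribed shapes.
fake_samples <- function(draws, term_of_column, deviance = NULL) {
  structure(list(
    chains = list(draws),
    deviance = deviance,
    accept = list(rep(NA_real_, 1)),
    param_names = colnames(draws),
    term_of_column = term_of_column,
    config = mcmc_config(n_chains = 1, n_burn = 0,
                         n_iter = max(1L, nrow(draws)))
  ), class = "posterior_samples")
}

fake_beta_fit <- function(draws, term_of_column, terms, design = NULL) {
  samples <- fake_samples(draws, term_of_column)
  structure(list(design = design, samples = samples, dic = NULL,
                 summary = summary(samples), terms = model_terms(terms)),
            class = "beta_fit")
}
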