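# MCMC driver and convergence diagnostics.

#' MCMC run configuration
#'
#' Defaults follow the analysis protocol: 3 chains, at least 8000 burn-in
#' adaptations and 4000 retained iterations per chain.  Shorter runs may be
#' requested explicitly (e.g. for model-selection screening).
#'
#' @param n_chains Number of chains (>= 1).
#' @param n_burn Burn-in iterations per chain (proposal adaptation happens
#'   only here).
#' @param n_iter Retained iterations per chain (> 0).
#' @param adapt_interval Iterations between proposal-scale updates.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_burn = 8000, n_iter = 4000,
                        adapt_interval = 50, seed = 1L) {
  stopifnot(n_chains >= 1, n_burn >= 0, adapt_interval >= 1)
  if (n_iter <= 0) stop("n_iter must be > 0")
  structure(list(n_chains = as.integer(n_chains), n_burn = as.integer(n_burn),
                 n_iter = as.integer(n_iter),
                 adapt_interval = as.integer(adapt_interval),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Draw posterior samples for the hierarchical beta regression
#'
#' Adaptive Metropolis-within-Gibbs with scalar Gaussian proposals over
#' blocks: each fixed effect, the random-intercept mean `mu_b`, each
#' non-singleton random intercept, `log(phi)` and `log(sigma2_b)`.
#' Proposal scales adapt toward roughly 35% acceptance during burn-in and
#' are frozen afterwards.  Initialization is deterministic: fixed effects
#' at 0, `mu_b` at the logit of the mean rescaled score, `phi` at its
#' method-of-moments estimate, random intercepts at `mu_b`.
#'
#' @param design A `model_design` from [build_design()].
#' @param priors A [beta_priors()] object.
#' @param config An [mcmc_config()] object.
#' @return Object of class `posterior_samples`: list with `chains` (one
#'   draw matrix per chain, one named column per parameter), `deviance`
#'   (per-chain vectors of the conditional deviance at each draw),
#'   `accept` (per-chain acceptance rates per block), `param_names`,
#'   `term_of_column`, and the `config`.
#' @export
sample_posterior <- function(design, priors = beta_priors(),
                             config = mcmc_config()) {
  stopifnot(inherits(design, "model_design"), inherits(config, "mcmc_config"))
  n <- length(design$y)
  if (n == 0) stop("design has no rows")
  p <- ncol(design$X)
  m <- length(design$singleton)

  ybar <- mean(design$y)
  v <- stats::var(design$y)
  phi0 <- max(ybar * (1 - ybar) / max(v, 1e-8) - 1, 0.05)
  init <- list(beta = numeric(p), mu_b = stats::qlogis(ybar),
               b = rep(stats::qlogis(ybar), m), phi = phi0, sigma2_b = 0.25)

  par_names <- c(colnames(design$X), "mu_b", "phi", "sigma2_b",
                 paste0("b_", seq_len(m)))
  chains <- vector("list", config$n_chains)
  devs <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    res <- sample_chain_cpp(design$y, design$X, design$participant,
                            design$singleton, unclass(priors), init,
                            config$n_burn, config$n_iter,
                            config$adapt_interval)
    dr <- res$draws
    colnames(dr) <- par_names
    chains[[ch]] <- dr
    devs[[ch]] <- as.numeric(res$deviance)
    accept[[ch]] <- as.numeric(res$accept)
  }
  structure(list(chains = chains, deviance = devs, accept = accept,
                 param_names = par_names,
                 term_of_column = design$term_of_column,
                 config = config),
            class = "posterior_samples")
}

#' Combine chains into one draw matrix
#' @param samples A `posterior_samples` object.
#' @return Matrix of stacked draws with named columns.
#' @export
combine_chains <- function(samples) {
  do.call(rbind, samples$chains)
}

#' Posterior summary table
#'
#' @param object A `posterior_samples` object.
#' @param params Optional subset of parameter names (defaults to all
#'   parameters except the individual random intercepts).
#' @param level Credible level for the equal-tailed interval.
#' @param ... Unused.
#' @return `data.frame` with mean, sd, median and interval bounds.
#' @export
summary.posterior_samples <- function(object, params = NULL, level = 0.95,
                                      ...) {
  all_draws <- combine_chains(object)
  if (is.null(params))
    params <- object$param_names[!grepl("^b_", object$param_names)]
  a <- (1 - level) / 2
  out <- data.frame(
    parameter = params,
    mean = colMeans(all_draws[, params, drop = FALSE]),
    sd = apply(all_draws[, params, drop = FALSE], 2, stats::sd),
    lower = apply(all_draws[, params, drop = FALSE], 2, stats::quantile,
                  probs = a),
    median = apply(all_draws[, params, drop = FALSE], 2, stats::median),
    upper = apply(all_draws[, params, drop = FALSE], 2, stats::quantile,
                  probs = 1 - a),
    row.names = NULL
  )
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain R-hat: each chain is halved, and the classical
#' between/within variance ratio is computed over the resulting sequences.
#' Values near 1 indicate between-chain agreement.
#'
#' @param chains List of numeric vectors (one parameter), or list of
#'   matrices with matching columns (R-hat per column).
#' @param split Halve each chain first (default `TRUE`).
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  if (is.list(chains) && is.matrix(chains[[1]])) {
    pn <- colnames(chains[[1]])
    out <- vapply(seq_len(ncol(chains[[1]])), function(j) {
      gelman_rubin(lapply(chains, function(m) m[, j]), split = split)
    }, numeric(1))
    names(out) <- pn
    return(out)
  }
  if (length(chains) < 2) stop("at least two chains are required")
  len <- unique(vapply(chains, length, integer(1)))
  if (length(len) != 1) stop("chains must have equal lengths")
  seqs <- chains
  if (split) {
    h <- floor(len / 2)
    seqs <- unlist(lapply(chains, function(x)
      list(x[seq_len(h)], x[seq.int(len - h + 1, len)])), recursive = FALSE)
  }
  nn <- length(seqs[[1]])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  vhat <- (nn - 1) / nn * W + B_over_n
  sqrt(vhat / W)
}

#' Sample autocorrelation of a chain
#'
#' @param chain Numeric vector.
#' @param lag Non-negative integer < length(chain).
#' @return Autocorrelation at the requested lag (1 at lag 0); `NA` with a
#'   warning for a constant chain.
#' @export
autocorrelation <- function(chain, lag) {
  stopifnot(lag >= 0, lag < length(chain))
  if (stats::sd(chain) == 0) {
    warning("autocorrelation undefined for a constant chain")
    return(NA_real_)
  }
  as.numeric(stats::acf(chain, lag.max = lag, plot = FALSE,
                        demean = TRUE)$acf[lag + 1])
}

#' Fit the hierarchical beta regression
#'
#' Convenience wrapper: builds the design for the requested terms, draws
#' posterior samples, and computes the DIC and a posterior summary.
#'
#' @param aset An `analysis_set`.
#' @param terms A [model_terms()] object or character vector.
#' @param priors A [beta_priors()].
#' @param config An [mcmc_config()].
#' @return Object of class `beta_fit`: list with `design`, `samples`,
#'   `dic`, `summary`, `terms`.
#' @export
fit_beta_model <- function(aset, terms, priors = beta_priors(),
                           config = mcmc_config()) {
  design <- build_design(aset, terms)
  samples <- sample_posterior(design, priors, config)
  dic <- compute_dic(samples, design)
  structure(list(design = design, samples = samples, dic = dic,
                 summary = summary(samples), terms = design$terms),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Hierarchical beta regression fit\n")
  cat("Terms:", if (length(x$terms)) paste(x$terms, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("DIC: %.2f (pD = %.2f)\n", x$dic$dic, x$dic$p_d))
  print(x$summary, digits = 3)
  invisible(x)
}

# Posterior-mean parameters of a fit, as a `params` list usable by
# log_posterior / model_deviance.
posterior_mean_params <- function(samples, design) {
  mu <- colMeans(combine_chains(samples))
  p <- ncol(design$X)
  list(beta = unname(mu[seq_len(p)]),
       mu_b = unname(mu["mu_b"]),
       phi = unname(mu["phi"]),
       sigma2_b = unname(mu["sigma2_b"]),
       b = unname(mu[paste0("b_", seq_along(design$singleton))]))
}
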