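# Mean-precision beta likelihood and the joint log posterior of the
# hierarchical model.

#' Log density of the mean-precision beta distribution
#'
#' Density of `Beta(mu * phi, (1 - mu) * phi)`, the parameterization in which
#' `mu` is the mean and `mu (1 - mu) / (1 + phi)` the variance.  Computed
#' exactly through log-gamma functions, including the normalizing constant.
#'
#' @param y Values in the open interval (0, 1).
#' @param mu Mean in (0, 1).
#' @param phi Precision, > 0.
#' @return Log density, vectorized over `y` / `mu`.
#' @export
beta_logpdf <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) stop("y must lie in the open interval (0, 1)")
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie in the open interval (0, 1)")
  if (any(phi <= 0)) stop("phi must be > 0")
  a <- mu * phi
  b <- (1 - mu) * phi
  (a - 1) * log(y) + (b - 1) * log1p(-y) - lgamma(a) - lgamma(b) + lgamma(phi)
}

#' Prior specification for the hierarchical beta regression
#'
#' Fixed effects and the random-intercept mean get zero-centred normal
#' priors; the beta precision `phi` and the random-intercept precision
#' `1 / sigma_b^2` get gamma priors with shape and scale both 1 (i.e.
#' Exponential(1)) by default.
#'
#' @param beta_var Prior variance of each fixed effect (default 1000).
#' @param mu_b_var Prior variance of the random-intercept mean (default 1000).
#' @param phi_shape,phi_scale Gamma prior on `phi`.
#' @param tau_shape,tau_scale Gamma prior on the random-intercept precision.
#' @return Object of class `beta_priors`.
#' @export
beta_priors <- function(beta_var = 1000, mu_b_var = 1000,
                        phi_shape = 1, phi_scale = 1,
                        tau_shape = 1, tau_scale = 1) {
  stopifnot(beta_var > 0, mu_b_var > 0, phi_shape > 0, phi_scale > 0,
            tau_shape > 0, tau_scale > 0)
  structure(list(beta_var = beta_var, mu_b_var = mu_b_var,
                 phi_shape = phi_shape, phi_scale = phi_scale,
                 tau_shape = tau_shape, tau_scale = tau_scale),
            class = "beta_priors")
}

# Linear predictor of the piecewise random-intercept model: singleton
# participants get the population mean mu_b, the rest their own b_i.
linear_predictor <- function(params, design) {
  icpt <- ifelse(design$singleton[design$participant] == 1,
                 params$mu_b, params$b[design$participant])
  eta <- icpt
  if (ncol(design$X) > 0) eta <- eta + drop(design$X %*% params$beta)
  eta
}

#' Joint log posterior of the hierarchical beta regression
#'
#' Sum of (i) the beta log likelihood of every observation with
#' `logit(mu_ij)` equal to the linear predictor (the piecewise intercept
#' being `mu_b` for single-assessment participants and `b_i` otherwise),
#' (ii) the normal log density of each non-singleton random intercept given
#' `(mu_b, sigma_b^2)`, and (iii) the prior log densities.  The gamma prior
#' on the random-intercept precision is expressed in terms of `sigma_b^2`
#' with the change-of-variables Jacobian included.
#'
#' @param params List with `beta` (length = ncol(X)), `mu_b`, `b` (one per
#'   participant; entries for singletons are ignored), `phi` (> 0),
#'   `sigma2_b` (> 0).
#' @param design A `model_design` from [build_design()].
#' @param priors A [beta_priors()] object.
#' @return Log posterior density (unnormalized), finite for interior values.
#' @export
log_posterior <- function(params, design, priors) {
  stopifnot(params$phi > 0, params$sigma2_b > 0,
            length(params$beta) == ncol(design$X))
  lp <- 0
  if (length(design$y) > 0) {
    mu <- stats::plogis(linear_predictor(params, design))
    lp <- lp + sum(beta_logpdf(design$y, mu, params$phi))
  }
  multi <- which(design$singleton == 0)
  if (length(multi))
    lp <- lp + sum(stats::dnorm(params$b[multi], params$mu_b,
                                sqrt(params$sigma2_b), log = TRUE))
  if (length(params$beta))
    lp <- lp + sum(stats::dnorm(params$beta, 0, sqrt(priors$beta_var),
                                log = TRUE))
  lp <- lp + stats::dnorm(params$mu_b, 0, sqrt(priors$mu_b_var), log = TRUE)
  lp <- lp + stats::dgamma(params$phi, shape = priors$phi_shape,
                           scale = priors$phi_scale, log = TRUE)
  # Gamma prior on tau = 1 / sigma2_b, with |d tau / d sigma2| = sigma2^-2.
  tau <- 1 / params$sigma2_b
  lp <- lp + stats::dgamma(tau, shape = priors$tau_shape,
                           scale = priors$tau_scale, log = TRUE) +
    2 * log(tau)
  lp
}

# Conditional deviance: -2 * beta log likelihood at the given parameters
# (random intercepts plugged in), used by the DIC machinery.
model_deviance <- function(params, design) {
  if (length(design$y) == 0) return(0)
  mu <- stats::plogis(linear_predictor(params, design))
  -2 * sum(beta_logpdf(design$y, mu, params$phi))
}
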