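# Conventional comparator: Gaussian random-intercept linear mixed model on
# the raw 0-37 score scale, with parametric-bootstrap fitted bands.

#' Fit the Gaussian random-intercept linear mixed model
#'
#' Fits `score ~ covariates + (1 | participant)` by maximum likelihood
#' (REML off, so likelihoods are comparable across mean structures) with
#' the same standardized covariates as the beta regression but the raw
#' 0-37 scores as the response.  If no participant has repeated
#' measurements the random intercept is unidentifiable; the model then
#' collapses to ordinary least squares with the random-intercept variance
#' pinned at 0 (with a warning).
#'
#' @param aset An `analysis_set`.
#' @param terms Model terms (see [model_terms()]).
#' @return Object of class `lmm_fit`: list with `coefficients` (a
#'   `data.frame` of estimates, SEs, z-approximation t and p values),
#'   `sigma2_b`, `sigma2_e`, `logLik`, the underlying `model`, plus design
#'   metadata.
#' @export
fit_lmm <- function(aset, terms) {
  design <- build_design(aset, terms)
  r <- aset$rows
  dat <- data.frame(score = r$bimc_score, design$X, pid = r$participant_id,
                    stringsAsFactors = FALSE, check.names = FALSE)
  covars <- colnames(design$X)
  has_repeats <- any(table(r$participant_id) > 1)
  rhs <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  if (has_repeats) {
    fml <- stats::as.formula(paste("score ~", rhs, "+ (1 | pid)"))
    model <- lme4::lmer(fml, data = dat, REML = FALSE)
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    vc <- as.data.frame(lme4::VarCorr(model))
    sigma2_b <- vc$vcov[vc$grp == "pid"]
    sigma2_e <- vc$vcov[vc$grp == "Residual"]
  } else {
    warning("no participant has repeated measurements; ",
            "random-intercept variance pinned at 0 (ordinary least squares)")
    fml <- stats::as.formula(paste("score ~", rhs))
    model <- stats::lm(fml, data = dat)
    est <- stats::coef(model)
    se <- sqrt(diag(stats::vcov(model)))
    sigma2_b <- 0
    sigma2_e <- summary(model)$sigma^2
  }
  if (any(!is.finite(se)))
    stop("singular design; offending column(s): ",
         paste(names(se)[!is.finite(se)], collapse = ", "))
  tval <- est / se
  coefs <- data.frame(
    parameter = names(est), estimate = unname(est), se = unname(se),
    t_value = unname(tval),
    p_value = unname(2 * stats::pnorm(-abs(tval))),
    row.names = NULL
  )
  structure(list(coefficients = coefs, sigma2_b = sigma2_b,
                 sigma2_e = sigma2_e, logLik = as.numeric(stats::logLik(model)),
                 model = model, has_repeats = has_repeats,
                 columns = covars, scaling = design$scaling,
                 contrast = aset$contrast, data = dat),
            class = "lmm_fit")
}

# Marginal LMM fitted score at a profile (no logit; can exceed [0, 37]).
lmm_fitted_profile <- function(est, fit, profile, ages) {
  V <- profile_term_values(profile, ages, fit$scaling)
  icpt <- est[["(Intercept)"]]
  covars <- setdiff(names(est), "(Intercept)")
  icpt + if (length(covars)) drop(V[, covars, drop = FALSE] %*% est[covars])
         else 0
}

#' Marginal fitted scores from the linear mixed model
#'
#' @param fit An `lmm_fit`.
#' @param profile A [covariate_profile()].
#' @param ages Age grid.
#' @return Fitted values on the score scale (not range-restricted).
#' @export
lmm_fitted_score <- function(fit, profile, ages) {
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$parameter)
  lmm_fitted_profile(est, fit, profile, ages)
}

#' Parametric-bootstrap confidence bands for LMM fitted values
#'
#' Simulates responses from the fitted model, refits, and recomputes the
#' marginal fitted values at the profile; the 2.5 / 97.5 percentiles over
#' bootstrap replicates form the band.  Refit failures are counted; more
#' than 5% failures aborts.
#'
#' @param fit An `lmm_fit`.
#' @param profile A [covariate_profile()].
#' @param ages Age grid.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed (bands are reproducible given the seed).
#' @return `data.frame` with `age`, `lower`, `median`, `upper`, and
#'   attribute `n_failed`.
#' @export
bootstrap_fitted_ci <- function(fit, profile, ages, B = 1000, seed = 1L) {
  stopifnot(B >= 100)
  set.seed(seed)
  sims <- stats::simulate(fit$model, nsim = B)
  boot <- matrix(NA_real_, nrow = B, ncol = length(ages))
  n_failed <- 0L
  for (bi in seq_len(B)) {
    est <- tryCatch({
      if (fit$has_repeats) {
        m <- lme4::refit(fit$model, newresp = sims[[bi]])
        lme4::fixef(m)
      } else {
        dat <- fit$data
        dat$score <- sims[[bi]]
        stats::coef(stats::lm(stats::formula(fit$model), data = dat))
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(est)) { n_failed <- n_failed + 1L; next }
    boot[bi, ] <- lmm_fitted_profile(est, fit, profile, ages)
  }
  if (n_failed > 0.05 * B)
    stop("bootstrap aborted: ", n_failed, " of ", B, " refits failed")
  qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  out <- data.frame(age = ages, lower = qs[1, ], median = qs[2, ],
                    upper = qs[3, ])
  attr(out, "n_failed") <- n_failed
  out
}

#' Compare the beta regression and LMM fits
#'
#' Both fits must come from the same analysis set.  Reports, for each
#' model, the residual sum of squares and explained variance of the
#' conditional per-row fitted scores (participant intercepts plugged in)
#' against the observed 0-37 scores, and the number of fitted values
#' falling outside the admissible [0, 37] range.  The beta model cannot
#' produce out-of-range values by construction; the Gaussian model can.
#'
#' @param beta_fit A `beta_fit`.
#' @param lmm_fit An `lmm_fit`.
#' @param aset The shared `analysis_set`.
#' @return `data.frame` with one row per model: `rss`,
#'   `explained_variance`, `n_out_of_range`.
#' @export
compare_models <- function(beta_fit, lmm_fit, aset) {
  obs <- aset$rows$bimc_score
  if (length(beta_fit$design$y) != length(obs) ||
      nrow(lmm_fit$data) != length(obs))
    stop("fits and analysis set have mismatched numbers of rows")
  fit_beta <- fitted_rows_beta(beta_fit)
  fit_lmm_v <- as.numeric(stats::fitted(lmm_fit$model))
  data.frame(
    model = c("beta_regression", "linear_mixed_model"),
    rss = c(residual_sum_squares(fit_beta, obs),
            residual_sum_squares(fit_lmm_v, obs)),
    explained_variance = c(explained_variance(fit_beta, obs),
                           explained_variance(fit_lmm_v, obs)),
    n_out_of_range = c(sum(fit_beta < 0 | fit_beta > 37),
                       sum(fit_lmm_v < 0 | fit_lmm_v > 37))
  )
}
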