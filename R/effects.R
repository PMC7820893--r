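# Interpretable summaries of a fitted model: fitted trajectories on the
# 0-37 score scale, onset-of-impairment ages, RSS and explained variance.

COEF_NAMES <- c("age", "age2", "sex", "edu", "apoe2", "apoe4",
                "age_edu", "age_apoe2", "age_apoe4",
                "edu_apoe2", "edu_apoe4")

# Fitted mean on the score scale.  The affine rescaling reserves 1% guard
# bands at each end of (0, 1); means inside a guard band map to the
# boundary score, so fitted values always lie in [0, 37].
score_from_mu <- function(mu) {
  out <- inverse_rescale(mu)
  out[out < 0] <- 0
  out[out > SCORE_MAX] <- SCORE_MAX
  out
}

#' A covariate profile for trajectory evaluation
#'
#' @param age Age(s) in years (the observed range is 91-113; values outside
#'   it trigger a warning where trajectories are evaluated).
#' @param sex `"female"` or `"male"`.
#' @param education_years Years of education.
#' @param allele_group `"e2"`, `"e3"`, or `"e4"`.
#' @return Object of class `covariate_profile`.
#' @export
covariate_profile <- function(age = NULL, sex = "female",
                              education_years = 12, allele_group = "e3") {
  stopifnot(sex %in% c("female", "male"),
            allele_group %in% c("e2", "e3", "e4"))
  structure(list(age = age, sex = sex, education_years = education_years,
                 allele_group = allele_group),
            class = "covariate_profile")
}

# Values of each coefficient's covariate at a profile, given the
# standardization constants; vectorized over age.
profile_term_values <- function(profile, age, scaling) {
  z_age <- (age - scaling$age_mean) / scaling$age_sd
  z_edu <- (profile$education_years - scaling$edu_mean) / scaling$edu_sd
  sx <- as.numeric(profile$sex == "male")
  g2 <- as.numeric(profile$allele_group == "e2")
  g4 <- as.numeric(profile$allele_group == "e4")
  cbind(age = z_age, age2 = z_age^2, sex = sx, edu = z_edu,
        apoe2 = g2, apoe4 = g4,
        age_edu = z_age * z_edu,
        age_apoe2 = z_age * g2, age_apoe4 = z_age * g4,
        edu_apoe2 = z_edu * g2, edu_apoe4 = z_edu * g4)
}

#' Marginal fitted score at a covariate profile
#'
#' Standardizes the profile with the stored scaling constants, forms the
#' linear predictor with intercept `mu_b` (the population-typical
#' participant), applies the inverse logit, and maps the fitted mean back
#' to the 0-37 score scale.  The result lies in (0, 37) by construction.
#'
#' @param params Named coefficients: must contain `mu_b` plus one entry per
#'   model coefficient (`age`, `sex`, `edu`, `apoe2`, `edu_apoe2`, ...).
#' @param profile A [covariate_profile()] (its `age` may be a vector, or
#'   supply `age` separately).
#' @param scaling List with `age_mean`, `age_sd`, `edu_mean`, `edu_sd`.
#' @param age Optional age vector overriding `profile$age`.
#' @return Fitted score(s) on the 0-37 scale.
#' @export
fitted_score <- function(params, profile, scaling, age = NULL) {
  params <- unlist(params)
  if (!"mu_b" %in% names(params)) stop("params must contain 'mu_b'")
  age <- if (is.null(age)) profile$age else age
  if (is.null(age)) stop("an age (or age grid) is required")
  if (any(age < 91 | age > 113))
    warning("evaluating the trajectory outside the observed 91-113 range")
  coefs <- params[setdiff(names(params), c("mu_b", "phi", "sigma2_b"))]
  coefs <- coefs[!grepl("^b_", names(coefs))]
  bad <- setdiff(names(coefs), COEF_NAMES)
  if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "))
  V <- profile_term_values(profile, age, scaling)
  eta <- params[["mu_b"]] +
    if (length(coefs)) drop(V[, names(coefs), drop = FALSE] %*% coefs) else 0
  score_from_mu(stats::plogis(eta))
}

#' Fitted trajectory with credible bands
#'
#' Evaluates the marginal fitted score for every posterior draw over an age
#' grid and returns pointwise 2.5 / 50 / 97.5 percentiles.  Because the
#' inverse-logit fitted mean is rescaled to (0, 37), the whole band always
#' respects the score bounds.
#'
#' @param samples A `posterior_samples` object.
#' @param profile A [covariate_profile()].
#' @param ages Age grid (years).
#' @param scaling Standardization constants (see [fitted_score()]).
#' @return `data.frame` with columns `age`, `lower`, `median`, `upper`.
#' @export
fitted_band <- function(samples, profile, ages, scaling) {
  draws <- combine_chains(samples)
  if (nrow(draws) == 0) stop("empty posterior samples")
  coef_cols <- intersect(colnames(draws), COEF_NAMES)
  V <- profile_term_values(profile, ages, scaling)
  eta <- matrix(draws[, "mu_b"], nrow = length(ages), ncol = nrow(draws),
                byrow = TRUE)
  if (length(coef_cols))
    eta <- eta + V[, coef_cols, drop = FALSE] %*%
      t(draws[, coef_cols, drop = FALSE])
  fit <- score_from_mu(stats::plogis(eta))
  qs <- t(apply(fit, 1, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  data.frame(age = ages, lower = qs[, 1], median = qs[, 2], upper = qs[, 3])
}

#' Age of onset of moderate impairment
#'
#' Finds the age(s) at which the fitted trajectory crosses the
#' moderate-impairment threshold (score 26 by default) within the observed
#' age range, by bisection to well below 0.01-year accuracy.  With a
#' curvature (`age2`) term the trajectory can cross twice; all crossings
#' are returned, each labelled `descending` (the clinically relevant
#' direction) or `ascending`.
#'
#' @param params Named coefficients (see [fitted_score()]).
#' @param profile A [covariate_profile()] without age.
#' @param scaling Standardization constants.
#' @param threshold Score threshold (default 26).
#' @param age_range Search interval (default `c(91, 113)`).
#' @return `data.frame` with columns `age` and `direction`; zero rows when
#'   the trajectory never crosses, with attribute `side` set to
#'   `"always_above"` or `"always_below"`.
#' @export
onset_age <- function(params, profile, scaling, threshold = 26,
                      age_range = c(91, 113)) {
  f <- function(a) fitted_score(params, profile, scaling, age = a) - threshold
  grid <- seq(age_range[1], age_range[2], by = 0.05)
  vals <- f(grid)
  out <- data.frame(age = numeric(0), direction = character(0))
  hits <- which(vals == 0)
  for (h in hits) {
    dirn <- if (h < length(vals) && vals[h + 1] < 0) "descending"
            else "ascending"
    out <- rbind(out, data.frame(age = grid[h], direction = dirn))
  }
  cross <- which(vals[-1] * vals[-length(vals)] < 0)
  for (cix in cross) {
    root <- stats::uniroot(f, c(grid[cix], grid[cix + 1]),
                           tol = 1e-8)$root
    dirn <- if (vals[cix] > 0) "descending" else "ascending"
    out <- rbind(out, data.frame(age = root, direction = dirn))
  }
  if (nrow(out) == 0)
    attr(out, "side") <- if (all(vals > 0)) "always_above" else "always_below"
  out[order(out$age), , drop = FALSE]
}

#' Residual sum of squares and explained variance
#'
#' `residual_sum_squares` is the sum of squared differences between
#' observed and fitted scores on the 0-37 scale.  `explained_variance` is
#' the regression sum of squares divided by the total sum of squares.
#'
#' @param fitted,observed Numeric vectors of equal length.
#' @return A single number.
#' @export
residual_sum_squares <- function(fitted, observed) {
  if (length(fitted) != length(observed)) stop("length mismatch")
  sum((observed - fitted)^2)
}

#' @rdname residual_sum_squares
#' @export
explained_variance <- function(fitted, observed) {
  if (length(fitted) != length(observed)) stop("length mismatch")
  sum((fitted - mean(observed))^2) / sum((observed - mean(observed))^2)
}

# Per-row conditional fitted scores of a beta fit (posterior-mean
# parameters, participant-specific intercepts plugged in), 0-37 scale.
fitted_rows_beta <- function(fit) {
  design <- fit$design
  pm <- posterior_mean_params(fit$samples, design)
  eta <- linear_predictor(pm, design)
  score_from_mu(stats::plogis(eta))
}
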