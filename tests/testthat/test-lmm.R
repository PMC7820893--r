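# Gaussian random-intercept comparator.

test_that("all-singleton data collapses to ordinary least squares", {
  cfg <- cohort_config(80, c(e2e3 = 0.25, e3e3 = 0.75),
                       followup_count_probs = c("1" = 1),
                       true_params = default_true_params(), seed = 41)
  aset <- make_analysis_set(generate_cohort(cfg), "e2_vs_e3")
  expect_warning(fit <- fit_lmm(aset, c("age", "edu")), "pinned at 0")
  expect_equal(fit$sigma2_b, 0)
  d <- build_design(aset, c("age", "edu"))
  ols <- lm(aset$rows$bimc_score ~ d$X)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("fixed effects solve the GLS equations at the fitted variances", {
  aset <- small_aset(120, seed = 42)
  fit <- fit_lmm(aset, c("age", "sex", "edu"))
  d <- build_design(aset, c("age", "sex", "edu"))
  X <- cbind(1, d$X)
  y <- aset$rows$bimc_score
  pid <- aset$rows$participant_index
  n <- length(y)
  V <- fit$sigma2_e * diag(n) +
    fit$sigma2_b * outer(pid, pid, `==`)
  gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  expect_equal(unname(fit$coefficients$estimate), unname(drop(gls)),
               tolerance = 1e-6)
})

test_that("variance components are recovered on simulated data", {
  # sigma_b = 3, sigma_e = 4, 300 participants with 2 observations each
  set.seed(43)
  n <- 300
  b <- rnorm(n, 0, 3)
  x <- rnorm(n)
  rows <- data.frame(
    participant_id = rep(sprintf("S%03d", 1:n), each = 2),
    participant_index = rep(1:n, each = 2),
    bimc_score = rep(20 + 1.5 * x, each = 2) + rep(b, each = 2) +
      rnorm(2 * n, 0, 4),
    z_age = rep(x, each = 2), z_age2 = rep(x^2, each = 2),
    sex_code = 0, z_edu = 0, group_e2 = 0, group_e4 = 0, i_single = 0,
    y_prime = 0.5, age_at_test = 103, education_years = 12
  )
  aset <- structure(list(rows = rows,
                         scaling = list(age_mean = 103, age_sd = 4,
                                        edu_mean = 12, edu_sd = 4),
                         contrast = "e2_vs_e3",
                         exclusion_log = NULL),
                    class = "analysis_set")
  fit <- fit_lmm(aset, "age")
  # 3-SE bounds for variance components in a balanced one-way design
  expect_lt(abs(fit$sigma2_b - 9), 3 * sqrt(2 / n) * (9 + 16 / 2))
  expect_lt(abs(fit$sigma2_e - 16), 3 * sqrt(2 / n) * 16)
  expect_lt(abs(fit$coefficients$estimate[2] - 1.5),
            3 * fit$coefficients$se[2])
})

test_that("bootstrap bands are reproducible and shrink with sample size", {
  prof <- covariate_profile(education_years = 12, allele_group = "e3")
  ages <- c(95, 103, 110)
  aset_small <- small_aset(60, seed = 44)
  fit_small <- fit_lmm(aset_small, c("age", "edu"))
  b1 <- bootstrap_fitted_ci(fit_small, prof, ages, B = 150, seed = 5)
  b2 <- bootstrap_fitted_ci(fit_small, prof, ages, B = 150, seed = 5)
  expect_equal(b1, b2)
  expect_error(bootstrap_fitted_ci(fit_small, prof, ages, B = 50), "B")

  aset_big <- small_aset(420, seed = 44)
  fit_big <- fit_lmm(aset_big, c("age", "edu"))
  b3 <- bootstrap_fitted_ci(fit_big, prof, ages, B = 150, seed = 5)
  # ~ 1/sqrt(n) narrowing: 7x the participants should at least halve widths
  expect_lt(mean(b3$upper - b3$lower), 0.75 * mean(b1$upper - b1$lower))
})

test_that("model comparison reports RSS, EV and boundary violations", {
  aset <- small_aset(80, seed = 45)
  terms <- c("age", "edu")
  bfit <- fit_beta_model(aset, terms,
                         config = mcmc_config(1, 600, 400, seed = 3))
  lfit <- fit_lmm(aset, terms)
  cmp <- compare_models(bfit, lfit, aset)
  obs <- aset$rows$bimc_score
  # RSS matches a naive recomputation from the per-row fitted values
  fb <- betacog:::fitted_rows_beta(bfit)
  expect_equal(cmp$rss[1], sum((obs - fb)^2), tolerance = 1e-10)
  expect_equal(cmp$rss[2], sum((obs - fitted(lfit$model))^2),
               tolerance = 1e-10)
  expect_equal(cmp$n_out_of_range[1], 0)
  expect_true(all(fb >= 0 & fb <= 37))
})

test_that("LMM fitted values can exceed the score ceiling; beta's cannot", {
  # Steep decline: scores near ceiling at the youngest ages.  The linear
  # marginal trajectory overshoots 37 when extrapolated to the young edge,
  # the logit-scale trajectory cannot.
  true <- true_params(mu_b = 1.6, sigma_b = 0.2, phi = 8,
                      betas = c(age = -0.9))
  cfg <- cohort_config(150, c(e3e3 = 1), age_mean = 100, age_sd = 4.5,
                       true_params = true, seed = 46)
  aset <- make_analysis_set(generate_cohort(cfg), "e2_vs_e3")
  bfit <- fit_beta_model(aset, "age",
                         config = mcmc_config(1, 800, 600, seed = 6))
  lfit <- fit_lmm(aset, "age")
  prof <- covariate_profile(education_years = 12, allele_group = "e3")
  ages <- seq(91, 113, by = 0.5)
  lmm_traj <- lmm_fitted_score(lfit, prof, ages)
  beta_traj <- fitted_band(bfit$samples, prof, ages, aset$scaling)
  expect_gt(max(lmm_traj), 37)
  expect_true(all(beta_traj$upper <= 37 & beta_traj$lower >= 0))
})
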