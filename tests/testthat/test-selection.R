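# DIC, backward selection, credible-interval refinement, prior sensitivity.

make_point_mass_samples <- function(design, params) {
  p <- ncol(design$X)
  row <- c(params$beta, params$mu_b, params$phi, params$sigma2_b, params$b)
  draws <- matrix(rep(row, each = 20), nrow = 20)
  colnames(draws) <- c(colnames(design$X), "mu_b", "phi", "sigma2_b",
                       paste0("b_", seq_along(design$singleton)))
  fake_samples(draws, design$term_of_column)
}

test_that("a point-mass posterior has p_d = 0 and dic = its deviance", {
  d <- random_design(4, 2, seed = 1)
  par <- random_params(d, seed = 2)
  s <- make_point_mass_samples(d, par)
  dic <- compute_dic(s, d)
  expect_equal(dic$p_d, 0, tolerance = 1e-10)
  mu <- plogis(ifelse(d$singleton[d$participant] == 1, par$mu_b,
                      par$b[d$participant]) + drop(d$X %*% par$beta))
  expect_equal(dic$dic, -2 * sum(beta_logpdf(d$y, mu, par$phi)),
               tolerance = 1e-10)
})

test_that("dic is invariant to permuting the draw order", {
  aset <- small_aset(40, seed = 7)
  d <- build_design(aset, c("age"))
  s <- sample_posterior(d, beta_priors(),
                        mcmc_config(n_chains = 1, n_burn = 300, n_iter = 200,
                                    seed = 5))
  dic1 <- compute_dic(s, d)
  set.seed(1)
  perm <- sample(nrow(s$chains[[1]]))
  s2 <- s
  s2$chains[[1]] <- s$chains[[1]][perm, ]
  s2$deviance[[1]] <- s$deviance[[1]][perm]
  dic2 <- compute_dic(s2, d)
  expect_equal(dic1$dic, dic2$dic, tolerance = 1e-10)
  expect_equal(dic1$p_d, dic2$p_d, tolerance = 1e-10)
  # and dic = dbar + p_d by construction
  expect_equal(dic1$dic, dic1$dbar + dic1$p_d)
  expect_error(compute_dic(fake_samples(s$chains[[1]][0, , drop = FALSE],
                                        d$term_of_column), d),
               "empty")
})

test_that("p_d approximates the free parameter count on a conjugate toy", {
  # Normal likelihood with known variance and flat-ish priors: pD ~ k.
  # Posterior draws simulated directly from the conjugate posterior, and
  # deviance computed per draw; this bypasses the beta machinery on purpose.
  set.seed(21)
  k <- 4; n_per <- 50; sigma <- 1
  theta_true <- rnorm(k)
  y <- lapply(1:k, function(j) rnorm(n_per, theta_true[j], sigma))
  post_mean <- vapply(y, mean, numeric(1))
  post_sd <- sigma / sqrt(n_per)
  n_draw <- 8000
  draws <- sapply(1:k, function(j) rnorm(n_draw, post_mean[j], post_sd))
  dev_draw <- apply(draws, 1, function(th)
    -2 * sum(unlist(lapply(1:k, function(j)
      dnorm(y[[j]], th[j], sigma, log = TRUE)))))
  dbar <- mean(dev_draw)
  d_at_mean <- -2 * sum(unlist(lapply(1:k, function(j)
    dnorm(y[[j]], mean(draws[, j]), sigma, log = TRUE))))
  p_d <- dbar - d_at_mean
  expect_lt(abs(p_d - k) / k, 0.15)
})

test_that("backward selection finds the exhaustive-minimum model", {
  # Strong age and edu effects, null sex effect.
  true <- true_params(mu_b = 0.6, sigma_b = 0.3, phi = 6,
                      betas = c(age = -0.35, edu = 0.3))
  aset <- small_aset(90, seed = 30, true = true)
  cfg <- mcmc_config(n_chains = 1, n_burn = 800, n_iter = 600, seed = 60)
  full <- model_terms(c("age", "sex", "edu"))
  sel <- backward_select(full, aset, beta_priors(), cfg)

  # exhaustive enumeration over all subsets of {age, sex, edu}
  subsets <- list(character(0), "age", "sex", "edu", c("age", "sex"),
                  c("age", "edu"), c("sex", "edu"), c("age", "sex", "edu"))
  dics <- vapply(subsets, function(tm)
    fit_beta_model(aset, tm, beta_priors(), cfg)$dic$dic, numeric(1))
  best <- min(dics)

  # MC noise in DIC across seeds: estimate from repeat fits of one model
  reps <- vapply(1:4, function(s)
    fit_beta_model(aset, c("age", "edu"), beta_priors(),
                   mcmc_config(1, 800, 600, seed = 200 + s))$dic$dic,
    numeric(1))
  mc_se <- sd(reps)
  expect_lt(sel$fit$dic$dic, best + 2 * max(mc_se, 1))
  expect_true(all(c("age", "edu") %in% unclass(sel$terms)))
})

test_that("a truly null interaction is usually removed", {
  # age x edu simulated at exactly 0; other effects present
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    true <- true_params(mu_b = 0.6, sigma_b = 0.3, phi = 6,
                        betas = c(age = -0.3, edu = 0.25, age_edu = 0))
    aset <- small_aset(80, seed = 300 + r, true = true)
    sel <- backward_select(model_terms(c("age", "edu", "age_edu")), aset,
                           beta_priors(),
                           mcmc_config(1, 1000, 800, seed = 400 + r))
    if (!"age_edu" %in% unclass(sel$terms)) hits <- hits + 1L
  }
  expect_gt(hits, n_rep / 2)
})

test_that("credible-interval pruning keeps significant terms and hierarchy", {
  # Posterior draws shaped like the published e2-analysis pattern: the main
  # APOE effect spans 0 but its interaction with education does not, so both
  # must be retained; a spanning-0 term without dependants is dropped.
  set.seed(50)
  n <- 4000
  draws <- cbind(
    age = rnorm(n, -0.110, 0.009),
    sex = rnorm(n, 0.262, 0.096),
    edu = rnorm(n, 0.062, 0.012),
    apoe2 = rnorm(n, 0.037, 0.088),      # CI spans 0
    edu_apoe2 = rnorm(n, -0.063, 0.023), # CI excludes 0
    age_edu = rnorm(n, 0.01, 0.05),      # CI spans 0, no dependants
    mu_b = rnorm(n, 0.592, 0.053),
    phi = rgamma(n, 50, 10),
    sigma2_b = rgamma(n, 20, 100)
  )
  toc <- c(age = "age", sex = "sex", edu = "edu", apoe2 = "apoe",
           edu_apoe2 = "edu_apoe", age_edu = "age_edu")
  fit <- fake_beta_fit(draws, toc,
                       c("age", "sex", "edu", "apoe", "edu_apoe", "age_edu"))
  kept <- refine_by_ci(fit)
  expect_setequal(unclass(kept), c("age", "sex", "edu", "apoe", "edu_apoe"))
  # output is a hierarchical subset of the input
  expect_true(all(unclass(kept) %in% unclass(fit$terms)))

  # simple drop / retain cases
  draws2 <- cbind(drop1 = rnorm(n, 0.05, 0.08), keep1 = rnorm(n, 0.17, 0.06),
                  mu_b = rnorm(n), phi = rgamma(n, 5, 1),
                  sigma2_b = rgamma(n, 2, 4))
  fit2 <- fake_beta_fit(draws2, c(drop1 = "age", keep1 = "sex"),
                        c("age", "sex"))
  expect_equal(unclass(refine_by_ci(fit2)), "sex")
})

test_that("prior sensitivity with a single setting reproduces the base fit", {
  aset <- small_aset(50, seed = 31)
  cfg <- mcmc_config(1, 500, 400, seed = 10)
  sens <- prior_sensitivity(aset, c("age"), list(base = beta_priors()), cfg)
  base <- fit_beta_model(aset, c("age"), beta_priors(), cfg)
  expect_equal(sens$table$mean, base$summary$mean, tolerance = 1e-12)
  expect_true(all(sens$max_shift_sd == 0))
})
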