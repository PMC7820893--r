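# Exclusions, allele grouping, rescaling, standardization, design matrices.

test_that("allele groups follow the genotype mapping, with e2e4 excluded", {
  expect_equal(assign_allele_group(c("e2e2", "e2e3")), c("e2", "e2"))
  expect_equal(assign_allele_group("e3e3"), "e3")
  expect_equal(assign_allele_group(c("e3e4", "e4e4")), c("e4", "e4"))
  expect_true(is.na(assign_allele_group("e2e4")))
  expect_error(assign_allele_group("e1e3"), "unknown genotype")
})

test_that("exclusions count each reason correctly and are idempotent", {
  cfg <- cohort_config(
    n_participants = 200,
    genotype_probs = c(e2e2 = 0.02, e2e3 = 0.2, e3e3 = 0.6, e3e4 = 0.1,
                       e4e4 = 0.02, e2e4 = 0.06),
    true_params = default_true_params(),
    missing_score_count = 23, missing_education_count = 17, seed = 31
  )
  coh <- generate_cohort(cfg)
  ex <- apply_exclusions(coh)

  # brute-force recount straight off the raw table
  by_id <- split(coh, coh$participant_id)
  miss_score <- sum(sapply(by_id, function(d) all(is.na(d$bimc_score))))
  rest <- by_id[sapply(by_id, function(d) !all(is.na(d$bimc_score)))]
  miss_edu <- sum(sapply(rest, function(d) all(is.na(d$education_years))))
  rest <- rest[sapply(rest, function(d) !all(is.na(d$education_years)))]
  n_e2e4 <- sum(sapply(rest, function(d) d$apoe_genotype[1] == "e2e4"))

  expect_equal(ex$log$n_excluded,
               c(miss_score, miss_edu, n_e2e4))
  expect_equal(ex$n_retained, 200 - miss_score - miss_edu - n_e2e4)

  ex2 <- apply_exclusions(ex$data)
  expect_equal(ex2$data, ex$data)
  expect_equal(ex2$log$n_excluded, c(0, 0, 0))
})

test_that("a cohort without missingness or e2e4 passes through unchanged", {
  coh <- generate_cohort(small_e2e3_config(n = 30, seed = 4))
  ex <- apply_exclusions(coh)
  expect_equal(nrow(ex$data), nrow(coh))
  expect_equal(ex$log$n_excluded, c(0, 0, 0))
})

test_that("score rescaling maps [0, 37] onto [0.01, 0.99] and inverts exactly", {
  expect_equal(rescale_score(0), 0.01)
  expect_equal(rescale_score(37), 0.99)
  expect_equal(rescale_score(18.5), 0.5)
  y <- 0:37
  expect_equal(inverse_rescale(rescale_score(y)), y)
  expect_true(all(diff(rescale_score(y)) > 0))
  expect_error(rescale_score(-1), "\\[0, 37\\]")
  expect_error(rescale_score(38), "\\[0, 37\\]")
})

test_that("standardization uses the n-1 sd and round-trips", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$z, c(-1, 0, 1))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  set.seed(9)
  x <- rnorm(50, 10, 3)
  s <- standardize(x)
  expect_equal(mean(s$z), 0, tolerance = 1e-12)
  expect_equal(sd(s$z), 1, tolerance = 1e-12)
  expect_equal(s$z * s$sd + s$mean, x, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("analysis set codes, scales and flags rows per the protocol", {
  coh <- generate_cohort(small_e2e3_config(n = 100, seed = 12))
  aset <- make_analysis_set(coh, "e2_vs_e3")
  r <- aset$rows
  expect_true(all(r$y_prime >= 0.01 & r$y_prime <= 0.99))
  expect_equal(mean(r$z_age), 0, tolerance = 1e-9)
  expect_equal(sd(r$z_age), 1, tolerance = 1e-9)
  # education standardized over participants, not rows
  per <- r[!duplicated(r$participant_id), ]
  expect_equal(mean(per$z_edu), 0, tolerance = 1e-9)
  expect_equal(sd(per$z_edu), 1, tolerance = 1e-9)
  expect_true(all(r$sex_code %in% c(0, 1)))
  n_obs <- table(r$participant_id)
  expect_equal(unname(r$i_single), unname(as.numeric(n_obs[r$participant_id] == 1)))
  # e4 carriers are absent under the e2-vs-e3 contrast
  expect_true(all(r$group_e4 == 0))
})

test_that("e2 and e4 dummies are never both set under the combined contrast", {
  cfg <- cohort_config(
    n_participants = 150,
    genotype_probs = c(e2e3 = 0.25, e3e3 = 0.55, e3e4 = 0.2),
    true_params = default_true_params(), seed = 13
  )
  aset <- make_analysis_set(generate_cohort(cfg), "all_three")
  expect_true(all(aset$rows$group_e2 + aset$rows$group_e4 <= 1))
  expect_true(any(aset$rows$group_e2 == 1) && any(aset$rows$group_e4 == 1))
})

test_that("model term hierarchy is enforced", {
  expect_error(model_terms(c("edu_apoe", "edu")), "requires parent")
  expect_error(model_terms("age2"), "requires parent")
  expect_silent(model_terms(c("age", "edu", "apoe", "edu_apoe", "age2")))
  expect_error(model_terms("height"), "unknown term")
})

test_that("design matrices have the expected columns and products", {
  coh <- generate_cohort(small_e2e3_config(n = 60, seed = 14))
  aset <- make_analysis_set(coh, "e2_vs_e3")

  d <- build_design(aset, c("age", "sex", "edu", "apoe", "edu_apoe"))
  expect_equal(colnames(d$X), c("age", "sex", "edu", "apoe2", "edu_apoe2"))
  expect_equal(d$X[, "edu_apoe2"], d$X[, "edu"] * d$X[, "apoe2"])

  d0 <- build_design(aset, character(0))
  expect_equal(ncol(d0$X), 0)
  expect_equal(length(d0$y), nrow(aset$rows))

  dfull <- build_design(aset, c("age", "age2", "sex", "edu", "apoe",
                                "age_edu", "age_apoe", "edu_apoe"))
  expect_equal(dfull$X[, "age_apoe2"], dfull$X[, "age"] * dfull$X[, "apoe2"])
  expect_equal(dfull$X[, "age_edu"], dfull$X[, "age"] * dfull$X[, "edu"])
  expect_equal(dfull$X[, "age2"], dfull$X[, "age"]^2)

  # all_three contrast carries both dummy sets
  cfg <- cohort_config(150, c(e2e3 = 0.25, e3e3 = 0.55, e3e4 = 0.2),
                       true_params = default_true_params(), seed = 13)
  aset3 <- make_analysis_set(generate_cohort(cfg), "all_three")
  d3 <- build_design(aset3, c("age", "edu", "apoe", "edu_apoe"))
  expect_true(all(c("apoe2", "apoe4", "edu_apoe2", "edu_apoe4") %in%
                    colnames(d3$X)))
  expect_error(build_design(aset3, c("edu_apoe", "edu")), "requires parent")
})
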