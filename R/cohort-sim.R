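# Synthetic longitudinal cohort generator -------------------------------------
#
# Emulates a centenarian cohort with annually repeated administrations of a
# bounded cognition screen (0-37), APOE genotypes, education and sex, and
# injectable missingness.  Outcomes are drawn from the hierarchical beta
# regression model that the rest of the package fits, so every downstream
# stage can be exercised against known truth.

GENOTYPES <- c("e2e2", "e2e3", "e3e3", "e3e4", "e4e4", "e2e4")

BETA_TERM_NAMES <- c(
  "age", "age2", "sex", "edu", "apoe2", "apoe4",
  "age_edu", "age_apoe2", "age_apoe4", "edu_apoe2", "edu_apoe4"
)

#' True generative parameters for the synthetic cohort
#'
#' Parameters of the hierarchical beta regression on the logit scale used to
#' simulate rescaled scores: `logit(mu_ij) = b_i + x_ij' beta`, with
#' `y'_ij ~ Beta(mu_ij * phi, (1 - mu_ij) * phi)`.  Participants with a
#' single assessment receive the population intercept `mu_b`; participants
#' with repeats draw `b_i ~ N(mu_b, sigma_b^2)`.
#'
#' @param mu_b Mean of the random intercepts (logit scale).
#' @param sigma_b Standard deviation of the random intercepts (>= 0).
#' @param phi Precision parameter of the beta distribution (> 0); the
#'   conditional variance of a rescaled score is `mu (1 - mu) / (1 + phi)`.
#' @param betas Named numeric vector of fixed effects on standardized
#'   covariates; names must come from
#'   `age, age2, sex, edu, apoe2, apoe4, age_edu, age_apoe2, age_apoe4,
#'   edu_apoe2, edu_apoe4`.  Unnamed terms default to 0.
#' @return An object of class `true_params`.
#' @export
true_params <- function(mu_b = 0, sigma_b = 0, phi = 10, betas = numeric(0)) {
  stopifnot(is.numeric(mu_b), length(mu_b) == 1L, is.finite(mu_b))
  if (!is.numeric(sigma_b) || sigma_b < 0) stop("sigma_b must be >= 0")
  if (!is.numeric(phi) || phi <= 0) stop("phi must be > 0")
  if (length(betas)) {
    bad <- setdiff(names(betas), BETA_TERM_NAMES)
    if (length(bad)) stop("unknown beta term(s): ", paste(bad, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(BETA_TERM_NAMES)), BETA_TERM_NAMES)
  full[names(betas)] <- betas
  structure(list(mu_b = mu_b, sigma_b = sigma_b, phi = phi, betas = full),
            class = "true_params")
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_participants Number of genotyped participants to generate.
#' @param genotype_probs Named probabilities over the six ordered-pair
#'   genotype strings (`e2e2, e2e3, e3e3, e3e4, e4e4, e2e4`); must sum to 1.
#'   Genotype composition is assigned by largest-remainder quota so that the
#'   realized counts equal `round(n * p)` up to the rounding rule; this keeps
#'   cohort accounting (including the rare e2e4 exclusions) reproducible.
#' @param age_mean,age_sd Mean and sd (years) of age at enrollment, truncated
#'   to `[age_min, age_max]`.
#' @param age_min,age_max Bounds of the observed age range (91-113 years).
#' @param education_probs Named probabilities over integer years of education.
#' @param p_male Probability of male sex.
#' @param followup_count_probs Named probabilities over the number of
#'   assessments per participant (names "1", "2", ...).
#' @param followup_spacing_years Spacing between assessments (annual = 1).
#' @param true_params A [true_params()] object.
#' @param missing_score_count Participants whose scores are all set missing.
#' @param missing_education_count Participants whose education is set missing
#'   (disjoint from the missing-score subset).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          genotype_probs,
                          age_mean = 103.3, age_sd = 4.5,
                          age_min = 91, age_max = 113,
                          education_probs = default_education_probs(),
                          p_male = 0.24,
                          followup_count_probs = default_followup_probs(),
                          followup_spacing_years = 1,
                          true_params = betacog::true_params(),
                          missing_score_count = 0,
                          missing_education_count = 0,
                          seed = 1L) {
  stopifnot(n_participants >= 0, missing_score_count >= 0,
            missing_education_count >= 0)
  if (abs(sum(genotype_probs) - 1) > 1e-9)
    stop("genotype_probs must sum to 1")
  bad <- setdiff(names(genotype_probs), GENOTYPES)
  if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  if (!(91 <= age_min && age_min < age_max && age_max <= 113))
    stop("age bounds must satisfy 91 <= min < max <= 113")
  if (abs(sum(education_probs) - 1) > 1e-9)
    stop("education_probs must sum to 1")
  if (abs(sum(followup_count_probs) - 1) > 1e-9)
    stop("followup_count_probs must sum to 1")
  if (followup_spacing_years <= 0) stop("followup spacing must be > 0")
  if (missing_score_count + missing_education_count > n_participants)
    stop("missingness counts exceed the number of participants")
  probs <- stats::setNames(numeric(length(GENOTYPES)), GENOTYPES)
  probs[names(genotype_probs)] <- genotype_probs
  structure(list(
    n_participants = as.integer(n_participants),
    genotype_probs = probs,
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    education_probs = education_probs,
    p_male = p_male,
    followup_count_probs = followup_count_probs,
    followup_spacing_years = followup_spacing_years,
    true_params = true_params,
    missing_score_count = as.integer(missing_score_count),
    missing_education_count = as.integer(missing_education_count),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default education distribution (integer years)
#'
#' Discrete distribution over 3-20 years calibrated so the quartiles are
#' 8 / 12 / 15 years, matching the low / median / high education profiles
#' used for fitted-trajectory summaries.
#' @return Named numeric vector of probabilities.
#' @export
default_education_probs <- function() {
  stats::setNames(
    c(0.01, 0.02, 0.03, 0.05, 0.06, 0.09, 0.06, 0.08, 0.05, 0.18,
      0.04, 0.05, 0.12, 0.08, 0.03, 0.04, 0.005, 0.005),
    as.character(3:20)
  )
}

#' Default assessment-count distribution
#'
#' 49% of participants complete only the baseline assessment (a consequence
#' of the high mortality at these ages); the remainder follow a geometric
#' tail over 2-8 annual assessments.
#' @return Named numeric vector of probabilities.
#' @export
default_followup_probs <- function() {
  tail_w <- 0.6^(0:6)
  p <- c(0.49, 0.51 * tail_w / sum(tail_w))
  stats::setNames(p, as.character(1:8))
}

#' Default true parameters shaped like the fitted centenarian models
#'
#' Fixed effects set to the posterior means of the final fitted models
#' (negative age effect, positive male and education effects, education by
#' APOE antagonism), with `phi` and `sigma_b` chosen so the marginal score
#' standard deviation is about 8 points on the 0-37 scale.
#' @return A [true_params()] object.
#' @export
default_true_params <- function() {
  true_params(
    mu_b = 0.592, sigma_b = 0.35, phi = 5,
    betas = c(age = -0.110, sex = 0.262, edu = 0.062,
              apoe2 = 0.037, edu_apoe2 = -0.063,
              apoe4 = -0.382, edu_apoe4 = -0.082)
  )
}

#' Default configuration emulating the centenarian study cohort
#'
#' 768 genotyped participants with genotype quotas whose complete-data subset
#' reproduces the study margins (117 / 331 / 38 participants in the e2 / e3 /
#' e4 allele groups and 4 e2e4 carriers), 167 participants with missing test
#' scores and 111 with missing education.  Sequential exclusion of the three
#' disjoint subsets leaves 486 participants.
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L) {
  cohort_config(
    n_participants = 768,
    genotype_probs = c(e2e2 = 8, e2e3 = 175, e3e3 = 523,
                       e3e4 = 58, e4e4 = 0, e2e4 = 4) / 768,
    true_params = default_true_params(),
    missing_score_count = 167,
    missing_education_count = 111,
    seed = seed
  )
}

# Largest-remainder apportionment of n into integer counts proportional to p.
quota_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws covariates and genotypes per participant, simulates rescaled scores
#' from the hierarchical beta model in [true_params()], maps them back to
#' integer 0-37 scores, and injects missingness on disjoint participant
#' subsets (missing scores first, then missing education), drawn from
#' non-e2e4 participants so that sequential exclusion accounting is exact.
#'
#' Covariates entering the linear predictor are standardized internally:
#' age over all test administrations, education over participants.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` (class `cohort`) with columns `participant_id`,
#'   `age_at_test`, `bimc_score`, `sex`, `education_years`, `apoe_genotype`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  empty <- data.frame(
    participant_id = character(0), age_at_test = numeric(0),
    bimc_score = integer(0), sex = character(0),
    education_years = integer(0), apoe_genotype = character(0),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("cohort", "data.frame")
  if (n == 0L) return(empty)

  set.seed(config$seed)
  counts <- quota_counts(n, config$genotype_probs)
  genotypes <- sample(rep(GENOTYPES, counts))

  # Disjoint missingness subsets, restricted to non-e2e4 carriers so that the
  # three exclusion reasons never overlap.
  pool <- which(genotypes != "e2e4")
  n_miss <- config$missing_score_count + config$missing_education_count
  if (n_miss > length(pool))
    stop("missingness counts exceed the number of non-e2e4 participants")
  miss_ids <- sample(pool, n_miss)
  miss_score <- miss_ids[seq_len(config$missing_score_count)]
  miss_edu <- setdiff(miss_ids, miss_score)

  # Scrambled per-participant stream seeds.  Consecutive integer seeds leave
  # Mersenne-Twister states under-mixed, which induces small systematic
  # cross-stream correlations between early draws (enough to correlate
  # education with age across participants); drawing the stream seeds from
  # the master stream removes that while keeping per-participant streams.
  seed_cov <- sample.int(.Machine$integer.max - 1L, n)
  seed_out <- sample.int(.Machine$integer.max - 1L, n)

  # First pass: covariates and visit structure, one RNG stream per participant.
  sex <- character(n); edu <- integer(n); n_visit <- integer(n)
  ages <- vector("list", n)
  edu_vals <- as.integer(names(config$education_probs))
  visit_vals <- as.integer(names(config$followup_count_probs))
  for (i in seq_len(n)) {
    set.seed(seed_cov[i])
    sex[i] <- if (stats::runif(1) < config$p_male) "male" else "female"
    edu[i] <- sample(edu_vals, 1, prob = config$education_probs)
    a0 <- rtruncnorm1(config$age_mean, config$age_sd,
                      config$age_min, config$age_max)
    k <- sample(visit_vals, 1, prob = config$followup_count_probs)
    a <- a0 + (seq_len(k) - 1) * config$followup_spacing_years
    ages[[i]] <- a[a <= config$age_max]
    n_visit[i] <- length(ages[[i]])
  }

  # Standardization constants over the realized cohort (age over rows,
  # education over participants), matching the preprocessing convention.
  all_ages <- unlist(ages)
  age_mu <- mean(all_ages); age_sd <- stats::sd(all_ages)
  edu_mu <- mean(edu); edu_sd <- stats::sd(edu)
  if (!is.finite(age_sd) || age_sd == 0) age_sd <- 1
  if (!is.finite(edu_sd) || edu_sd == 0) edu_sd <- 1

  tp <- config$true_params
  b <- tp$betas
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed_out[i])
    a <- ages[[i]]
    z_age <- (a - age_mu) / age_sd
    z_edu <- (edu[i] - edu_mu) / edu_sd
    sx <- as.numeric(sex[i] == "male")
    g2 <- as.numeric(genotypes[i] %in% c("e2e2", "e2e3"))
    g4 <- as.numeric(genotypes[i] %in% c("e3e4", "e4e4"))
    eta <- b["age"] * z_age + b["age2"] * z_age^2 + b["sex"] * sx +
      b["edu"] * z_edu + b["apoe2"] * g2 + b["apoe4"] * g4 +
      b["age_edu"] * z_age * z_edu +
      b["age_apoe2"] * z_age * g2 + b["age_apoe4"] * z_age * g4 +
      b["edu_apoe2"] * z_edu * g2 + b["edu_apoe4"] * z_edu * g4
    intercept <- if (n_visit[i] > 1L)
      stats::rnorm(1, tp$mu_b, tp$sigma_b) else tp$mu_b
    mu <- stats::plogis(intercept + eta)
    yp <- stats::rbeta(length(a), mu * tp$phi, (1 - mu) * tp$phi)
    score <- pmin(37L, pmax(0L, as.integer(round(inverse_rescale(yp)))))
    rows[[i]] <- data.frame(
      participant_id = sprintf("P%04d", i),
      age_at_test = a,
      bimc_score = score,
      sex = sex[i],
      education_years = edu[i],
      apoe_genotype = genotypes[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$bimc_score[out$participant_id %in% sprintf("P%04d", miss_score)] <- NA_integer_
  out$education_years[out$participant_id %in% sprintf("P%04d", miss_edu)] <- NA_integer_
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write / read a cohort as CSV
#'
#' Lossless round trip: empty fields encode missing scores or education.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort` returns a validated cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("participant_id", "age_at_test", "bimc_score", "sex",
            "education_years", "apoe_genotype")
  stopifnot(all(cols %in% names(cohort)))
  utils::write.csv(as.data.frame(cohort)[, cols], path,
                   row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(
                           participant_id = "character",
                           age_at_test = "numeric",
                           bimc_score = "integer",
                           sex = "character",
                           education_years = "integer",
                           apoe_genotype = "character"
                         ),
                         fileEncoding = "UTF-8")
  bad_score <- which(!is.na(out$bimc_score) &
                       (out$bimc_score < 0 | out$bimc_score > 37))
  if (length(bad_score))
    stop("bimc_score out of range [0, 37] at row(s): ",
         paste(bad_score, collapse = ", "))
  bad_gt <- which(!out$apoe_genotype %in% GENOTYPES)
  if (length(bad_gt))
    stop("unknown apoe_genotype at row(s): ", paste(bad_gt, collapse = ", "))
  bad_sex <- which(!out$sex %in% c("female", "male"))
  if (length(bad_sex))
    stop("sex must be 'female' or 'male' at row(s): ",
         paste(bad_sex, collapse = ", "))
  class(out) <- c("cohort", "data.frame")
  out
}
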