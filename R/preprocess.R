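# Exclusions, allele grouping, coding, standardization, score rescaling,
# and design-matrix construction.

SCORE_MAX <- 37

TERM_NAMES <- c("age", "age2", "sex", "edu", "apoe",
                "age_edu", "age_apoe", "edu_apoe")

TERM_PARENTS <- list(
  age2 = "age",
  age_edu = c("age", "edu"),
  age_apoe = c("age", "apoe"),
  edu_apoe = c("edu", "apoe")
)

#' Map an APOE genotype to its allele group
#'
#' Because homozygote e2 and e4 carriers are rare, genotypes are analysed in
#' three allele groups: e2 = \{e2e2, e2e3\}, e3 = \{e3e3\} (the reference),
#' e4 = \{e3e4, e4e4\}.  The ambiguous e2e4 genotype belongs to no group and
#' is excluded from analysis (returned as `NA`).
#'
#' @param genotype Character vector of ordered-pair genotype strings.
#' @return Character vector with values `"e2"`, `"e3"`, `"e4"`, or `NA` for
#'   e2e4.
#' @export
assign_allele_group <- function(genotype) {
  bad <- setdiff(unique(genotype), GENOTYPES)
  if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  out <- rep(NA_character_, length(genotype))
  out[genotype %in% c("e2e2", "e2e3")] <- "e2"
  out[genotype == "e3e3"] <- "e3"
  out[genotype %in% c("e3e4", "e4e4")] <- "e4"
  out
}

#' Apply cohort exclusions
#'
#' Removes, in order: participants with no observed score, participants with
#' missing education, then e2e4 carriers, and logs the participant count
#' removed per reason.  Exclusion is idempotent.
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]).
#' @return A list with elements `data` (the retained rows) and `log` (a
#'   `data.frame` of `reason`, `n_excluded`), plus `n_retained`.
#' @export
apply_exclusions <- function(cohort) {
  dat <- as.data.frame(cohort)
  by_id <- split(dat, dat$participant_id)
  no_score <- names(by_id)[vapply(by_id, function(d) all(is.na(d$bimc_score)),
                                  logical(1))]
  dat <- dat[!dat$participant_id %in% no_score, , drop = FALSE]

  by_id <- split(dat, dat$participant_id)
  no_edu <- names(by_id)[vapply(by_id, function(d) all(is.na(d$education_years)),
                                logical(1))]
  dat <- dat[!dat$participant_id %in% no_edu, , drop = FALSE]

  e2e4 <- unique(dat$participant_id[dat$apoe_genotype == "e2e4"])
  dat <- dat[!dat$participant_id %in% e2e4, , drop = FALSE]

  # Drop any remaining rows with a missing score (participants who keep at
  # least one observed score stay in).
  dat <- dat[!is.na(dat$bimc_score), , drop = FALSE]
  rownames(dat) <- NULL
  list(
    data = dat,
    log = data.frame(
      reason = c("missing_score", "missing_education", "genotype_e2e4"),
      n_excluded = c(length(no_score), length(no_edu), length(e2e4))
    ),
    n_retained = length(unique(dat$participant_id))
  )
}

#' Rescale a 0-37 score into the open unit interval
#'
#' The beta distribution is supported on (0, 1); observed scores on
#' \[0, 37\] are mapped affinely onto \[0.01, 0.99\] so that the boundary
#' scores 0 and 37 avoid the open-interval endpoints:
#' `y' = 0.01 + 0.98 * y / 37`.  `inverse_rescale` is the exact inverse.
#'
#' @param y Scores on the 0-37 scale.
#' @param y_prime Rescaled values.
#' @return Rescaled values in \[0.01, 0.99\] (or scores for the inverse).
#' @export
rescale_score <- function(y) {
  if (any(y < 0 | y > SCORE_MAX)) stop("scores must lie in [0, 37]")
  0.01 + 0.98 * y / SCORE_MAX
}

#' @rdname rescale_score
#' @export
inverse_rescale <- function(y_prime) {
  (y_prime - 0.01) * SCORE_MAX / 0.98
}

#' Standardize a numeric vector
#'
#' Centres and scales by the sample standard deviation (n - 1 denominator),
#' returning the constants needed to invert the transformation.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return List with `z`, `mean`, `sd`.
#' @export
standardize <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Construct a validated set of model terms
#'
#' Candidate fixed-effect terms are the main effects `age`, `sex`, `edu`,
#' `apoe`, the curvature term `age2`, and the two-way interactions
#' `age_edu`, `age_apoe`, `edu_apoe`.  An interaction (and `age2`) may only
#' be included together with its parent main effects.
#'
#' @param included Character vector of term names.
#' @return Object of class `model_terms`.
#' @export
model_terms <- function(included = character(0)) {
  bad <- setdiff(included, TERM_NAMES)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  included <- TERM_NAMES[TERM_NAMES %in% included]
  for (tm in intersect(included, names(TERM_PARENTS))) {
    missing_par <- setdiff(TERM_PARENTS[[tm]], included)
    if (length(missing_par))
      stop("term '", tm, "' requires parent term(s): ",
           paste(missing_par, collapse = ", "))
  }
  structure(included, class = "model_terms")
}

#' Build an analysis set from a cohort
#'
#' Applies exclusions, assigns allele groups, restricts to the requested
#' contrast (`e2_vs_e3` keeps the e2 and e3 groups, `e4_vs_e3` the e4 and e3
#' groups, `all_three` keeps all), standardizes age (over all retained test
#' administrations) and education (over participants), codes sex 0 = female /
#' 1 = male, adds allele-group dummies with e3 as reference, rescales scores
#' to (0, 1), and flags participants with a single assessment.
#'
#' @param cohort A cohort `data.frame`.
#' @param contrast One of `"e2_vs_e3"`, `"e4_vs_e3"`, `"all_three"`.
#' @return Object of class `analysis_set`: list with `rows` (a `data.frame`),
#'   `scaling` (age/edu means and sds), `contrast`, and `exclusion_log`.
#' @export
make_analysis_set <- function(cohort, contrast = c("e2_vs_e3", "e4_vs_e3",
                                                   "all_three")) {
  contrast <- match.arg(contrast)
  excl <- apply_exclusions(cohort)
  dat <- excl$data
  dat$allele_group <- assign_allele_group(dat$apoe_genotype)
  keep_groups <- switch(contrast,
    e2_vs_e3 = c("e2", "e3"),
    e4_vs_e3 = c("e3", "e4"),
    all_three = c("e2", "e3", "e4")
  )
  dat <- dat[dat$allele_group %in% keep_groups, , drop = FALSE]
  if (nrow(dat) == 0) stop("no rows left after exclusions and contrast filter")

  age_std <- standardize(dat$age_at_test)
  per_part <- dat[!duplicated(dat$participant_id), ]
  edu_std <- standardize(per_part$education_years)
  edu_z_by_id <- stats::setNames(edu_std$z, per_part$participant_id)
  n_obs <- table(dat$participant_id)

  rows <- data.frame(
    participant_id = dat$participant_id,
    participant_index = match(dat$participant_id,
                              unique(dat$participant_id)),
    age_at_test = dat$age_at_test,
    bimc_score = dat$bimc_score,
    y_prime = rescale_score(dat$bimc_score),
    z_age = age_std$z,
    z_age2 = age_std$z^2,
    sex_code = as.numeric(dat$sex == "male"),
    z_edu = unname(edu_z_by_id[dat$participant_id]),
    education_years = dat$education_years,
    group_e2 = as.numeric(dat$allele_group == "e2"),
    group_e4 = as.numeric(dat$allele_group == "e4"),
    i_single = as.numeric(n_obs[dat$participant_id] == 1L),
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  structure(list(
    rows = rows,
    scaling = list(age_mean = age_std$mean, age_sd = age_std$sd,
                   edu_mean = edu_std$mean, edu_sd = edu_std$sd),
    contrast = contrast,
    exclusion_log = excl$log
  ), class = "analysis_set")
}

#' Write an analysis set to CSV plus a JSON sidecar
#'
#' @param aset An `analysis_set`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @export
write_analysis_set <- function(aset, path) {
  utils::write.csv(aset$rows, path, row.names = FALSE, na = "")
  meta <- list(contrast = aset$contrast, scaling = aset$scaling,
               exclusion_log = aset$exclusion_log)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build the fixed-effect design matrix for a model
#'
#' One row per test administration.  Columns follow the term order: main
#' effects, then `age2`, then interactions; the APOE term expands to the e2
#' dummy under contrast `e2_vs_e3`, the e4 dummy under `e4_vs_e3`, and both
#' dummies under `all_three` (interactions with APOE expand likewise).  The
#' intercept is not a column: it enters the linear predictor through the
#' piecewise random-intercept device.
#'
#' @param aset An `analysis_set`.
#' @param terms A [model_terms()] object (or character vector of terms).
#' @return List of class `model_design`: `X` (matrix), `y` (rescaled scores),
#'   `participant` (integer index), `singleton` (0/1 per participant),
#'   `term_of_column` (term behind each column), `terms`, `contrast`,
#'   `scaling`.
#' @export
build_design <- function(aset, terms) {
  stopifnot(inherits(aset, "analysis_set"))
  terms <- model_terms(unclass(terms))
  r <- aset$rows
  apoe_cols <- switch(aset$contrast,
    e2_vs_e3 = list(apoe2 = r$group_e2),
    e4_vs_e3 = list(apoe4 = r$group_e4),
    all_three = list(apoe2 = r$group_e2, apoe4 = r$group_e4)
  )
  cols <- list(); term_of <- character(0)
  add <- function(cols, term_of, name, term, value) {
    cols[[name]] <- value
    term_of[name] <- term
    list(cols = cols, term_of = term_of)
  }
  for (tm in terms) {
    upd <- switch(tm,
      age = add(cols, term_of, "age", "age", r$z_age),
      age2 = add(cols, term_of, "age2", "age2", r$z_age2),
      sex = add(cols, term_of, "sex", "sex", r$sex_code),
      edu = add(cols, term_of, "edu", "edu", r$z_edu),
      apoe = {
        tmp <- list(cols = cols, term_of = term_of)
        for (nm in names(apoe_cols))
          tmp <- add(tmp$cols, tmp$term_of, nm, "apoe", apoe_cols[[nm]])
        tmp
      },
      age_edu = add(cols, term_of, "age_edu", "age_edu", r$z_age * r$z_edu),
      age_apoe = {
        tmp <- list(cols = cols, term_of = term_of)
        for (nm in names(apoe_cols))
          tmp <- add(tmp$cols, tmp$term_of, paste0("age_", nm), "age_apoe",
                     r$z_age * apoe_cols[[nm]])
        tmp
      },
      edu_apoe = {
        tmp <- list(cols = cols, term_of = term_of)
        for (nm in names(apoe_cols))
          tmp <- add(tmp$cols, tmp$term_of, paste0("edu_", nm), "edu_apoe",
                     r$z_edu * apoe_cols[[nm]])
        tmp
      }
    )
    cols <- upd$cols; term_of <- upd$term_of
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(r), ncol = 0)
  colnames(X) <- names(cols)
  singleton <- tapply(r$i_single, r$participant_index, function(v) v[1])
  structure(list(
    X = X,
    y = r$y_prime,
    participant = r$participant_index,
    singleton = as.numeric(singleton[order(as.integer(names(singleton)))]),
    term_of_column = term_of,
    terms = terms,
    contrast = aset$contrast,
    scaling = aset$scaling
  ), class = "model_design")
}
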