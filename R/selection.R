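# DIC, backward model selection, credible-interval refinement, and
# prior-sensitivity refits.

#' Deviance information criterion of a fitted model
#'
#' Conditional DIC: the deviance is -2 times the beta log likelihood with
#' the random intercepts plugged in.  `dbar` is the posterior mean deviance,
#' `d_at_mean` the deviance at the posterior mean of all parameters
#' (including the random intercepts), `p_d = dbar - d_at_mean` the effective
#' number of parameters, and `dic = dbar + p_d`.
#'
#' @param samples A `posterior_samples` object.
#' @param design The `model_design` the samples were drawn for.
#' @return Object of class `dic_result` with fields `dbar`, `d_at_mean`,
#'   `p_d`, `dic`.
#' @export
compute_dic <- function(samples, design) {
  if (length(samples$chains) == 0 || nrow(samples$chains[[1]]) == 0)
    stop("empty posterior samples")
  if (!is.null(samples$deviance) && length(samples$deviance)) {
    dbar <- mean(unlist(samples$deviance))
  } else {
    all_draws <- combine_chains(samples)
    p <- ncol(design$X)
    devs <- apply(all_draws, 1, function(row) {
      model_deviance(list(beta = unname(row[seq_len(p)]),
                          mu_b = unname(row["mu_b"]),
                          phi = unname(row["phi"]),
                          sigma2_b = unname(row["sigma2_b"]),
                          b = unname(row[paste0("b_",
                                                seq_along(design$singleton))])),
                     design)
    })
    dbar <- mean(devs)
  }
  d_at_mean <- model_deviance(posterior_mean_params(samples, design), design)
  p_d <- dbar - d_at_mean
  structure(list(dbar = dbar, d_at_mean = d_at_mean, p_d = p_d,
                 dic = dbar + p_d),
            class = "dic_result")
}

# Terms that can be dropped without violating hierarchy: a term is droppable
# when no other included term lists it as a parent.
droppable_terms <- function(terms) {
  terms <- unclass(terms)
  parents_in_use <- unique(unlist(TERM_PARENTS[intersect(terms,
                                                         names(TERM_PARENTS))]))
  setdiff(terms, parents_in_use)
}

#' Backward model selection by DIC
#'
#' Starts from the full candidate model and repeatedly removes the single
#' droppable term (interactions and the curvature term before their parent
#' main effects) whose removal most decreases the DIC; stops when no removal
#' decreases it.  All candidate fits within one step share the same seed so
#' DIC differences are not dominated by seed noise.  Exact ties are broken
#' by dropping the higher-order term first, then alphabetically.
#'
#' @param full A [model_terms()] object (the starting model).
#' @param aset An `analysis_set`.
#' @param priors A [beta_priors()].
#' @param config An [mcmc_config()]; step `s` uses seed `config$seed + s`.
#' @return Object of class `selection_trace`: list with `trace` (a
#'   `data.frame` of every candidate evaluated), `terms` (the selected
#'   [model_terms()]), and `fit` (the fit of the selected model).
#' @export
backward_select <- function(full, aset, priors = beta_priors(),
                            config = mcmc_config()) {
  current <- model_terms(unclass(full))
  step_cfg <- function(s) mcmc_config(config$n_chains, config$n_burn,
                                      config$n_iter, config$adapt_interval,
                                      seed = config$seed + s)
  fit_cur <- fit_beta_model(aset, current, priors, step_cfg(0L))
  trace <- data.frame(step = 0L, dropped = NA_character_,
                      terms = paste(current, collapse = "+"),
                      dic = fit_cur$dic$dic, decision = "start",
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- droppable_terms(current)
    if (!length(cand)) break
    # higher-order terms first, then alphabetical, for deterministic ties
    ord <- order(!cand %in% names(TERM_PARENTS), cand)
    cand <- cand[ord]
    fits <- lapply(cand, function(tm) {
      tryCatch(fit_beta_model(aset, setdiff(unclass(current), tm), priors,
                              step_cfg(step)),
               error = function(e)
                 stop("fit failed after dropping '", tm, "' from {",
                      paste(current, collapse = ", "), "}: ",
                      conditionMessage(e)))
    })
    dics <- vapply(fits, function(f) f$dic$dic, numeric(1))
    best <- which.min(dics)
    improved <- dics[best] < fit_cur$dic$dic
    trace <- rbind(trace, data.frame(
      step = step, dropped = cand,
      terms = vapply(fits, function(f) paste(f$terms, collapse = "+"),
                     character(1)),
      dic = dics,
      decision = ifelse(seq_along(cand) == best,
                        if (improved) "dropped" else "kept (no improvement)",
                        "candidate"),
      stringsAsFactors = FALSE))
    if (!improved) break
    current <- model_terms(setdiff(unclass(current), cand[best]))
    fit_cur <- fits[[best]]
  }
  structure(list(trace = trace, terms = current, fit = fit_cur),
            class = "selection_trace")
}

# Equal-tailed credible intervals per model term (a multi-column term, e.g.
# APOE under the three-group contrast, is summarized column by column).
term_cis <- function(fit, level = 0.95) {
  draws <- combine_chains(fit$samples)
  a <- (1 - level) / 2
  cols <- names(fit$samples$term_of_column)
  data.frame(
    column = cols,
    term = unname(fit$samples$term_of_column[cols]),
    lower = vapply(cols, function(cn) stats::quantile(draws[, cn], a),
                   numeric(1)),
    upper = vapply(cols, function(cn) stats::quantile(draws[, cn], 1 - a),
                   numeric(1)),
    row.names = NULL
  )
}

#' Refine a selected model by credible intervals
#'
#' DIC search tends to overfit, so the selected model is pruned: a term is
#' retained when the equal-tailed credible interval of at least one of its
#' coefficients excludes 0, and a main effect is additionally retained
#' whenever a surviving interaction (or the curvature term) contains it.
#' The output is always a hierarchical subset of the input terms; the
#' pruned model should be refit (see [select_model()]).
#'
#' @param fit A `beta_fit` for the model to prune.
#' @param level Credible level (default 0.95).
#' @return A [model_terms()] object.
#' @export
refine_by_ci <- function(fit, level = 0.95) {
  cis <- term_cis(fit, level)
  sig_terms <- unique(cis$term[cis$lower > 0 | cis$upper < 0])
  keep <- intersect(unclass(fit$terms), sig_terms)
  # close under hierarchy
  repeat {
    need <- unique(unlist(TERM_PARENTS[intersect(keep, names(TERM_PARENTS))]))
    add <- setdiff(intersect(need, unclass(fit$terms)), keep)
    if (!length(add)) break
    keep <- c(keep, add)
  }
  model_terms(keep)
}

#' Full model-selection pipeline
#'
#' Backward DIC search followed by credible-interval pruning and one refit
#' of the pruned model.
#'
#' @inheritParams backward_select
#' @param level Credible level used in the pruning stage.
#' @return List with `search` (the [backward_select()] trace), `terms`
#'   (final [model_terms()]), and `fit` (the final refit).
#' @export
select_model <- function(full, aset, priors = beta_priors(),
                         config = mcmc_config(), level = 0.95) {
  search <- backward_select(full, aset, priors, config)
  refined <- refine_by_ci(search$fit, level)
  fit <- if (identical(unclass(refined), unclass(search$terms)))
    search$fit
  else
    fit_beta_model(aset, refined, priors, config)
  list(search = search, terms = refined, fit = fit)
}

#' Prior-sensitivity refits
#'
#' Refits the same model under a grid of prior settings and reports the
#' posterior means and credible intervals side by side, together with the
#' largest absolute shift of each parameter's posterior mean relative to
#' the first grid entry, in units of that parameter's posterior sd.
#'
#' @param aset An `analysis_set`.
#' @param terms Model terms.
#' @param prior_grid Named list of [beta_priors()] objects; the first entry
#'   is the reference.
#' @param config An [mcmc_config()] (the same seed is used for every refit).
#' @return List with `table` (long-format summary per prior setting) and
#'   `max_shift_sd` (named vector, one entry per parameter).
#' @export
prior_sensitivity <- function(aset, terms, prior_grid,
                              config = mcmc_config()) {
  stopifnot(length(prior_grid) >= 1)
  if (is.null(names(prior_grid)))
    names(prior_grid) <- paste0("prior_", seq_along(prior_grid))
  fits <- lapply(seq_along(prior_grid), function(i) {
    tryCatch(fit_beta_model(aset, terms, prior_grid[[i]], config),
             error = function(e)
               stop("fit failed under prior setting '",
                    names(prior_grid)[i], "': ", conditionMessage(e)))
  })
  tabs <- lapply(seq_along(fits), function(i) {
    s <- fits[[i]]$summary
    s$prior <- names(prior_grid)[i]
    s
  })
  table <- do.call(rbind, tabs)
  base <- fits[[1]]$summary
  shift <- rep(0, nrow(base)); names(shift) <- base$parameter
  for (i in seq_along(fits)[-1]) {
    s <- fits[[i]]$summary
    shift <- pmax(shift, abs(s$mean - base$mean) / base$sd)
  }
  list(table = table, max_shift_sd = shift)
}
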