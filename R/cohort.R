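
#' Default parameter priors for synthetic cohorts
#'
#' Distributions the cohort generator draws subject-level parameters from.
#' Medians are anchored to the magnitudes typically recovered from human
#' data on this task (temperature around 0.15, learning rates around 1/3,
#' a broad spread of normalization weights): `beta` is log-normal with
#' median 0.15, `alpha_f ~ Beta(2, 4)`, `alpha_c ~ Beta(2, 6)`,
#' `omega ~ Uniform(0, 1)`, `upsilon ~ Uniform(0.1, 1)`. Each prior is a
#' list with a `dist` field (`"lnorm"`, `"beta"`, `"unif"` or `"fixed"`)
#' and its parameters; pass modified entries to [cohort_config()] to change
#' a prior, or `list(dist = "fixed", value = x)` for a point mass.
#'
#' @return a named list of prior specifications.
#' @export
default_priors <- function() {
  list(
    beta    = list(dist = "lnorm", meanlog = log(0.15), sdlog = 0.5),
    alpha_f = list(dist = "beta", shape1 = 2, shape2 = 4),
    alpha_c = list(dist = "beta", shape1 = 2, shape2 = 6),
    omega   = list(dist = "unif", min = 0, max = 1),
    upsilon = list(dist = "unif", min = 0.1, max = 1)
  )
}

draw_prior <- function(prior, n = 1L) {
  switch(prior$dist,
    lnorm = rlnorm(n, prior$meanlog, prior$sdlog),
    beta  = rbeta(n, prior$shape1, prior$shape2),
    unif  = runif(n, prior$min, prior$max),
    fixed = rep(prior$value, n),
    stop("unknown prior distribution: ", prior$dist, call. = FALSE)
  )
}

#' Configuration of a synthetic cohort
#'
#' @param n_exp1 number of Experiment-1-style subjects (partial feedback
#'   only; default 20).
#' @param n_exp2 number of Experiment-2-style subjects (50% complete
#'   feedback trials; default 40).
#' @param model generating model, one of [MODEL_NAMES], recycled over
#'   subjects (so a vector mixes generating models within the cohort).
#' @param priors parameter priors; see [default_priors()].
#' @param seed master seed. Subject-level streams are derived from it with
#'   [stable_seed()], so enlarging the cohort never changes existing
#'   subjects' data.
#' @param outcome_mode `"bernoulli"` or `"exact"`; see [simulate_agent()].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_exp1 = 20L, n_exp2 = 40L, model = "HYBRID",
                          priors = default_priors(), seed = 1L,
                          outcome_mode = "bernoulli") {
  stopifnot(n_exp1 >= 0, n_exp2 >= 0, n_exp1 + n_exp2 >= 1)
  model <- vapply(model, function(m) match.arg(m, MODEL_NAMES), character(1))
  base <- default_priors()
  base[names(priors)] <- priors
  structure(list(n_exp1 = as.integer(n_exp1), n_exp2 = as.integer(n_exp2),
                 model = unname(model), priors = base, seed = as.integer(seed),
                 outcome_mode = outcome_mode),
            class = "cohort_config")
}

#' Draw one subject's generating parameters from the cohort priors
#'
#' Draws are truncated/validated against the parameter bounds
#' (`beta` clamped to \[1e-3, 100\]); parameters the model does not use are
#' `NA`, and `alpha_c` is drawn only for Experiment-2-style subjects.
#'
#' @param config a [cohort_config()].
#' @param model generating model for this subject.
#' @param experiment 1 or 2.
#' @return a [model_params()] object. Uses the current RNG state.
#' @export
sample_parameters <- function(config, model = config$model[1], experiment = 2) {
  pr <- config$priors
  beta <- min(max(draw_prior(pr$beta), 1e-3), 100)
  model_params(
    model,
    beta = beta,
    alpha_f = draw_prior(pr$alpha_f),
    alpha_c = if (experiment == 2) draw_prior(pr$alpha_c) else NA_real_,
    omega = if (model == "HYBRID") draw_prior(pr$omega) else NA_real_,
    upsilon = if (model == "UTILITY") draw_prior(pr$upsilon) else NA_real_
  )
}

#' Generate a synthetic multi-subject cohort with known ground truth
#'
#' For every subject: parameters are drawn from the priors, fresh session
#' and transfer schedules are built, and [simulate_agent()] produces the
#' behavioral data — 2 sessions x 80 learning trials and 112 transfer
#' trials per subject. Experiment-1 subjects see partial feedback
#' everywhere; Experiment-2 subjects see the forgone outcome on 50% of
#' trials.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory; when given, `learning.csv`,
#'   `transfer.csv` and `ground_truth.csv` are written there.
#' @return a list with tibbles `learning`, `transfer` and `ground_truth`
#'   (one row per subject: generating model and true parameters).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_exp1 + config$n_exp2
  experiment <- rep(c(1L, 2L), c(config$n_exp1, config$n_exp2))
  ids <- sprintf("e%d_s%02d", experiment,
                 c(seq_len(config$n_exp1), seq_len(config$n_exp2)))
  models <- rep_len(config$model, n)

  learning <- vector("list", n); transfer <- vector("list", n); truth <- vector("list", n)
  for (i in seq_len(n)) {
    seed_par <- stable_seed(config$seed, ids[i], salt = 1L)
    seed_sched <- stable_seed(config$seed, ids[i], salt = 2L)
    seed_sim <- stable_seed(config$seed, ids[i], salt = 3L)
    params <- with_seed(seed_par, sample_parameters(config, models[i], experiment[i]))
    sched <- build_subject_schedules(experiment[i], seed_sched)
    sim <- simulate_agent(params, sched, seed_sim, subject_id = ids[i],
                          outcome_mode = config$outcome_mode)
    learning[[i]] <- sim$learning
    transfer[[i]] <- sim$transfer
    truth[[i]] <- tibble::tibble(
      subject_id = ids[i], experiment = experiment[i], model = models[i],
      beta = params$beta, alpha_f = params$alpha_f, alpha_c = params$alpha_c,
      omega = params$omega, upsilon = params$upsilon
    )
  }

  out <- list(learning = dplyr::bind_rows(learning),
              transfer = dplyr::bind_rows(transfer),
              ground_truth = dplyr::bind_rows(truth))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_learning_trials(out$learning, file.path(dir, "learning.csv"))
    write_transfer_trials(out$transfer, file.path(dir, "transfer.csv"))
    readr::write_csv(out$ground_truth, file.path(dir, "ground_truth.csv"), na = "")
  }
  out
}
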