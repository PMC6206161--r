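
#' Bayesian Information Criterion
#'
#' `BIC = 2 * NLL + ln(ntrials) * df` with the natural logarithm, where
#' `ntrials` is the number of choices entering the likelihood (160 for the
#' learning sessions, 112 for the transfer test, 272 for both).
#'
#' @param nll negative log-likelihood at the optimum.
#' @param df number of free parameters.
#' @param ntrials number of trials in the fitting scope.
#' @export
bic <- function(nll, df, ntrials) {
  stopifnot(ntrials >= 1, df >= 0)
  2 * nll + log(ntrials) * df
}

# Free parameters of a model in fitting order, with optimization box and the
# conventional start point (temperature 1, rates/weights 0.5).
param_spec <- function(model, has_complete) {
  model <- match.arg(model, MODEL_NAMES)
  nm <- c("beta", "alpha_f")
  if (has_complete) nm <- c(nm, "alpha_c")
  if (model == "HYBRID") nm <- c(nm, "omega")
  if (model == "UTILITY") nm <- c(nm, "upsilon")
  lower <- c(beta = 1e-3, alpha_f = 0, alpha_c = 0, omega = 0, upsilon = 0.1)[nm]
  upper <- c(beta = 100, alpha_f = 1, alpha_c = 1, omega = 1, upsilon = 1)[nm]
  start <- c(beta = 1, alpha_f = 0.5, alpha_c = 0.5, omega = 0.5, upsilon = 0.5)[nm]
  list(names = nm, lower = lower, upper = upper, start = start)
}

vec_to_params <- function(model, x, nm) {
  g <- function(p, default = NA_real_) if (p %in% nm) unname(x[match(p, nm)]) else default
  model_params(model, beta = g("beta"), alpha_f = g("alpha_f"),
               alpha_c = g("alpha_c"), omega = g("omega"), upsilon = g("upsilon"))
}

# Deterministic low-discrepancy start points inside the box: coordinate k of
# start j is frac(j * sqrt(prime_k)), with the temperature mapped through a
# log10 scale so starts cover its box multiplicatively.
extra_starts <- function(spec, n) {
  if (n < 1) return(NULL)
  primes <- c(2, 3, 5, 7, 11, 13)[seq_along(spec$names)]
  m <- sapply(seq_len(n), function(j) (j * sqrt(primes)) %% 1)
  m <- matrix(m, nrow = length(spec$names))
  out <- spec$lower + m * (spec$upper - spec$lower)
  i <- match("beta", spec$names)
  out[i, ] <- 10^(-3 + m[i, ] * (log10(spec$upper[i]) + 3))
  rownames(out) <- spec$names
  out
}

scope_ntrials <- function(scope, prep) {
  switch(scope,
         learning_only = length(prep$ctx),
         transfer_only = length(prep$t_opt_c),
         both = length(prep$ctx) + length(prep$t_opt_c))
}

#' Maximum-likelihood fit of one model to one subject
#'
#' Bounded local optimization (L-BFGS-B) of the negative log-likelihood,
#' started from the conventional point (temperature 1, learning rates and
#' weights 0.5) plus `n_starts - 1` deterministic low-discrepancy points
#' inside the parameter box; the best run is kept. Bounds: beta in
#' \[1e-3, 100\], learning rates and omega in \[0, 1\], upsilon in
#' \[0.1, 1\]. The counterfactual rate `alpha_c` is included only when the
#' data contain complete-feedback trials, which also determines `df`.
#'
#' @param learning one subject's learning trials.
#' @param transfer the subject's transfer trials (required unless
#'   `scope = "learning_only"`).
#' @param model one of [MODEL_NAMES].
#' @param scope fitting scope, see [negative_log_likelihood()].
#' @param n_starts number of optimization starts (default 10).
#' @return a one-row tibble: subject and model identity, fitted parameters,
#'   `nll`, `df`, `ntrials`, `bic`, `n_starts`, `converged`.
#' @export
fit_subject <- function(learning, transfer = NULL, model = "HYBRID",
                        scope = c("both", "learning_only", "transfer_only"),
                        n_starts = 10L) {
  scope <- match.arg(scope)
  model <- match.arg(model, MODEL_NAMES)
  prep <- prepare_subject_data(learning, transfer)
  spec <- param_spec(model, any(prep$shown_u))
  nm <- spec$names

  obj <- function(x) {
    x <- pmin(pmax(x, spec$lower), spec$upper)
    nll_prepared(vec_to_params(model, x, nm), prep, scope)
  }

  starts <- cbind(spec$start, extra_starts(spec, n_starts - 1L))
  best <- NULL; any_ok <- FALSE
  for (j in seq_len(ncol(starts))) {
    res <- tryCatch(
      optim(starts[, j], obj, method = "L-BFGS-B",
            lower = spec$lower, upper = spec$upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    any_ok <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!any_ok)
    stop("optimization failed on all ", ncol(starts), " starts for subject ",
         learning$subject_id[1], ", model ", model, call. = FALSE)

  pars <- stats::setNames(rep(NA_real_, 5),
                          c("beta", "alpha_f", "alpha_c", "omega", "upsilon"))
  pars[nm] <- best$par
  ntrials <- scope_ntrials(scope, prep)
  tibble::tibble(
    subject_id = learning$subject_id[1],
    experiment = prep$experiment,
    model = model, scope = scope,
    beta = pars[["beta"]], alpha_f = pars[["alpha_f"]], alpha_c = pars[["alpha_c"]],
    omega = pars[["omega"]], upsilon = pars[["upsilon"]],
    nll = best$value, df = length(nm), ntrials = ntrials,
    bic = bic(best$value, length(nm), ntrials),
    n_starts = ncol(starts), converged = best$convergence == 0
  )
}

#' Exhaustive grid-search reference optimizer
#'
#' Evaluates the negative log-likelihood on a full factorial grid over the
#' model's parameter box (temperature log-spaced, other parameters evenly
#' spaced, endpoints included) and returns the best grid point. Intended as
#' a brute-force reference to certify [fit_subject()]; a local optimizer
#' must reach at least the best grid point's likelihood.
#'
#' @inheritParams fit_subject
#' @param n_points grid points per parameter axis.
#' @return a list with `params` (named vector of the best grid point) and
#'   `nll`.
#' @export
grid_search_oracle <- function(learning, transfer = NULL, model = "HYBRID",
                               scope = c("both", "learning_only", "transfer_only"),
                               n_points = 11L) {
  scope <- match.arg(scope)
  model <- match.arg(model, MODEL_NAMES)
  prep <- prepare_subject_data(learning, transfer)
  spec <- param_spec(model, any(prep$shown_u))
  axes <- lapply(seq_along(spec$names), function(k) {
    if (spec$names[k] == "beta") {
      10^seq(log10(spec$lower[k]), log10(spec$upper[k]), length.out = n_points)
    } else {
      seq(spec$lower[k], spec$upper[k], length.out = n_points)
    }
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  best_nll <- Inf; best <- NULL
  for (i in seq_len(nrow(grid))) {
    v <- nll_prepared(vec_to_params(model, grid[i, ], spec$names), prep, scope)
    if (v < best_nll) { best_nll <- v; best <- grid[i, ] }
  }
  list(params = stats::setNames(best, spec$names), nll = best_nll)
}

#' Fit a set of models to every subject of a cohort
#'
#' Runs [fit_subject()] for each subject x model x scope cell and stacks the
#' results. Per-subject optimization failures are propagated as flagged rows
#' (`converged = NA`) rather than aborting the cohort.
#'
#' @param learning learning trials of all subjects.
#' @param transfer transfer trials of all subjects (or `NULL` for
#'   `scopes = "learning_only"`).
#' @param models character vector of models to fit.
#' @param scopes character vector of fitting scopes.
#' @inheritParams fit_subject
#' @return a tibble of [fit_subject()] rows.
#' @export
fit_cohort <- function(learning, transfer = NULL, models = MODEL_NAMES,
                       scopes = "both", n_starts = 10L) {
  subjects <- unique(learning$subject_id)
  rows <- list()
  for (sid in subjects) {
    ls <- learning[learning$subject_id == sid, , drop = FALSE]
    ts <- if (!is.null(transfer)) transfer[transfer$subject_id == sid, , drop = FALSE]
    for (m in models) for (sc in scopes) {
      row <- tryCatch(
        fit_subject(ls, ts, model = m, scope = sc, n_starts = n_starts),
        error = function(e) {
          tibble::tibble(subject_id = sid, experiment = ls$experiment[1],
                         model = m, scope = sc,
                         beta = NA_real_, alpha_f = NA_real_, alpha_c = NA_real_,
                         omega = NA_real_, upsilon = NA_real_,
                         nll = NA_real_, df = NA_integer_, ntrials = NA_integer_,
                         bic = NA_real_, n_starts = n_starts, converged = NA)
        }
      )
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarize cohort BICs as mean and standard error per cell
#'
#' @param fits a [fit_cohort()] table.
#' @param by_experiment split cells by experiment as well.
#' @return a tibble with `model`, `scope` (and `experiment`), `n`,
#'   `bic_mean`, `bic_sem`.
#' @export
bic_summary <- function(fits, by_experiment = FALSE) {
  keys <- c(if (by_experiment) "experiment", "model", "scope")
  fits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(),
                     bic_mean = mean(.data$bic),
                     bic_sem = sd(.data$bic) / sqrt(dplyr::n()),
                     .groups = "drop")
}
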