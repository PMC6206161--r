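
# Convert one subject's trial tables into the integer-indexed arrays the
# likelihood core consumes. Options and contexts are indexed against the
# experiment's option catalog; learning trials are normalized to
# session/trial order.
prepare_subject_data <- function(learning, transfer = NULL, experiment = NULL) {
  stopifnot(is.data.frame(learning), nrow(learning) > 0)
  if (length(unique(learning$subject_id)) > 1)
    stop("prepare_subject_data expects a single subject", call. = FALSE)
  experiment <- experiment %||% learning$experiment[1]
  catalog <- option_catalog(experiment)
  learning <- learning[order(learning$session, learning$trial), , drop = FALSE]

  bad_choice <- !learning$choice %in% c("left", "right")
  if (any(bad_choice))
    stop("learning `choice` must be 'left' or 'right' (first bad row: ",
         which(bad_choice)[1], ")", call. = FALSE)
  chosen <- ifelse(learning$choice == "left", learning$option_left, learning$option_right)
  unchosen <- ifelse(learning$choice == "left", learning$option_right, learning$option_left)

  opt_c <- match(chosen, catalog$option)
  opt_u <- match(unchosen, catalog$option)
  if (anyNA(opt_c) || anyNA(opt_u))
    stop("unknown option identifier in learning trials", call. = FALSE)
  ctx_ids <- unique(catalog$context_id)
  ctx <- match(learning$context_id, ctx_ids)
  if (anyNA(ctx)) stop("unknown context_id in learning trials", call. = FALSE)
  ok_ctx <- catalog$context_id[opt_c] == learning$context_id &
    catalog$context_id[opt_u] == learning$context_id
  if (!all(ok_ctx))
    stop("option shown outside its context (first bad row: ", which(!ok_ctx)[1], ")",
         call. = FALSE)

  out_u <- learning$outcome_unchosen
  shown_u <- !is.na(out_u)
  out_u[!shown_u] <- 0

  if (!is.null(transfer) && nrow(transfer) > 0) {
    if (!all(transfer$choice %in% c("a", "b")))
      stop("transfer `choice` must be 'a' or 'b'", call. = FALSE)
    t_chosen <- ifelse(transfer$choice == "a", transfer$option_a, transfer$option_b)
    t_other <- ifelse(transfer$choice == "a", transfer$option_b, transfer$option_a)
    t_opt_c <- match(t_chosen, catalog$option)
    t_opt_u <- match(t_other, catalog$option)
    if (anyNA(t_opt_c) || anyNA(t_opt_u))
      stop("unknown option identifier in transfer trials", call. = FALSE)
  } else {
    t_opt_c <- t_opt_u <- integer()
  }

  list(experiment = experiment, catalog = catalog,
       context_ids = ctx_ids, options = catalog$option,
       session = learning$session, trial = learning$trial,
       ctx = ctx, opt_c = opt_c, opt_u = opt_u,
       out_c = learning$outcome_chosen, out_u = out_u, shown_u = shown_u,
       t_opt_c = t_opt_c, t_opt_u = t_opt_u)
}

model_code <- function(model) match(match.arg(model, MODEL_NAMES), MODEL_NAMES)

# Map a model_params object onto the scalar arguments of the C++ core,
# substituting inert values for parameters the model does not use.
params_for_core <- function(params, any_complete) {
  stopifnot(inherits(params, "model_params"))
  alpha_c <- params$alpha_c
  if (any_complete && is.na(alpha_c))
    stop("data contain complete-feedback trials: alpha_c is required", call. = FALSE)
  if (is.na(alpha_c)) alpha_c <- 0
  list(model = model_code(params$model), beta = params$beta,
       alpha_f = params$alpha_f, alpha_c = alpha_c,
       omega = params$omega %|NA|% 0, upsilon = params$upsilon %|NA|% 1)
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Negative log-likelihood of a subject's choices under a model
#'
#' Replays the subject's fixed choice/outcome history: on every learning
#' trial the probability of the made choice is computed from the current
#' option values via the model's choice rule, after which the state value
#' and option values are updated from the observed outcome(s). Transfer
#' choices are evaluated against the frozen post-learning values (no
#' updates). The learning phase is always replayed — even for
#' `scope = "transfer_only"` — because transfer choices can only be
#' evaluated with learned values; the scope controls which trials enter the
#' sum.
#'
#' @param params a [model_params()] object.
#' @param learning one subject's learning trials (see [read_learning_trials()]
#'   for the schema).
#' @param transfer the subject's transfer trials, or `NULL`.
#' @param scope `"learning_only"` (160 trials), `"transfer_only"` (112) or
#'   `"both"` (272).
#' @return the negative log-likelihood (choice probabilities are floored at
#'   1e-15 before taking logs).
#' @export
negative_log_likelihood <- function(params, learning, transfer = NULL,
                                    scope = c("both", "learning_only", "transfer_only")) {
  scope <- match.arg(scope)
  prep <- prepare_subject_data(learning, transfer)
  nll_prepared(params, prep, scope)
}

# Likelihood on pre-indexed data (hot path used by the optimizer).
nll_prepared <- function(params, prep, scope) {
  if (scope != "learning_only" && length(prep$t_opt_c) == 0)
    stop("scope '", scope, "' requires transfer trials", call. = FALSE)
  pc <- params_for_core(params, any(prep$shown_u))
  res <- replay_nll_cpp(pc$model, pc$beta, pc$alpha_f, pc$alpha_c, pc$omega, pc$upsilon,
                        prep$ctx, prep$opt_c, prep$opt_u,
                        prep$out_c, prep$out_u, prep$shown_u,
                        length(prep$options), length(prep$context_ids),
                        prep$t_opt_c, prep$t_opt_u)
  switch(scope,
         learning_only = res$nll_learning,
         transfer_only = res$nll_transfer,
         both = res$nll_learning + res$nll_transfer)
}

#' Replay a subject's history with full per-trial traces
#'
#' Reference implementation of the likelihood replay, in pure R, returning
#' everything the trial-wise analyses need: per-trial choice probabilities,
#' encoded outcomes, prediction errors, and option values before and after
#' each update, plus the frozen post-learning values used for the transfer
#' phase. The compiled core used during fitting is required (and tested) to
#' agree with this function to numerical precision.
#'
#' @inheritParams negative_log_likelihood
#' @return a list with elements `nll`, `nll_learning`, `nll_transfer`,
#'   `traces` (tibble, one row per learning trial), `transfer_traces`
#'   (tibble with the probability of each transfer choice), `Q` (named
#'   vector of final option values) and `V` (named vector of state values).
#' @export
replay_likelihood <- function(params, learning, transfer = NULL,
                              scope = c("both", "learning_only", "transfer_only")) {
  scope <- match.arg(scope)
  prep <- prepare_subject_data(learning, transfer)
  pc <- params_for_core(params, any(prep$shown_u))
  model <- params$model
  n <- length(prep$ctx)

  Q <- stats::setNames(numeric(length(prep$options)), prep$options)
  V <- stats::setNames(numeric(length(prep$context_ids)), prep$context_ids)
  tr <- tibble::tibble(
    session = prep$session, trial = prep$trial,
    context_id = prep$context_ids[prep$ctx],
    option_chosen = prep$options[prep$opt_c],
    option_unchosen = prep$options[prep$opt_u],
    p_choice = NA_real_, log_p = NA_real_,
    r_encoded_chosen = NA_real_, r_encoded_unchosen = NA_real_,
    delta_chosen = NA_real_, delta_unchosen = NA_real_,
    q_before_chosen = NA_real_, q_after_chosen = NA_real_,
    q_before_unchosen = NA_real_, q_after_unchosen = NA_real_
  )

  for (i in seq_len(n)) {
    c_i <- prep$opt_c[i]; u_i <- prep$opt_u[i]; s_i <- prep$ctx[i]
    qc <- Q[[c_i]]; qu <- Q[[u_i]]
    p <- choice_prob(model, qc, qu, pc$beta)
    tr$p_choice[i] <- p
    tr$log_p[i] <- log(max(p, 1e-15))

    v <- V[[s_i]]
    v <- update_state_value(v, prep$out_c[i])
    if (prep$shown_u[i]) v <- update_state_value(v, prep$out_u[i])
    V[[s_i]] <- v

    rc <- encode_outcome(model, prep$out_c[i], v, pc$omega, pc$upsilon)
    tr$r_encoded_chosen[i] <- rc
    tr$delta_chosen[i] <- rc - qc
    tr$q_before_chosen[i] <- qc
    Q[[c_i]] <- q_update(qc, rc, pc$alpha_f)
    tr$q_after_chosen[i] <- Q[[c_i]]
    tr$q_before_unchosen[i] <- qu
    if (prep$shown_u[i]) {
      ru <- encode_outcome(model, prep$out_u[i], v, pc$omega, pc$upsilon)
      tr$r_encoded_unchosen[i] <- ru
      tr$delta_unchosen[i] <- ru - qu
      Q[[u_i]] <- q_update(qu, ru, pc$alpha_c)
    }
    tr$q_after_unchosen[i] <- Q[[u_i]]
  }

  if (length(prep$t_opt_c) > 0) {
    p_t <- vapply(seq_along(prep$t_opt_c), function(i) {
      choice_prob(model, Q[[prep$t_opt_c[i]]], Q[[prep$t_opt_u[i]]], pc$beta)
    }, numeric(1))
    ttr <- tibble::tibble(
      trial = seq_along(p_t),
      option_chosen = prep$options[prep$t_opt_c],
      option_other = prep$options[prep$t_opt_u],
      p_choice = p_t, log_p = log(pmax(p_t, 1e-15))
    )
  } else {
    ttr <- tibble::tibble(trial = integer(), option_chosen = character(),
                          option_other = character(), p_choice = numeric(),
                          log_p = numeric())
  }

  nll_l <- -sum(tr$log_p)
  nll_t <- -sum(ttr$log_p)
  nll <- switch(scope, learning_only = nll_l, transfer_only = nll_t, both = nll_l + nll_t)
  list(nll = nll, nll_learning = nll_l, nll_transfer = nll_t,
       traces = tr, transfer_traces = ttr, Q = Q, V = V)
}

#' Build the complete trial schedules for one subject
#'
#' Two learning sessions (80 trials each, four fixed pairs per session) and
#' the 112-trial transfer schedule over the final session's 8 options.
#'
#' @param experiment 1 or 2.
#' @param seed integer; session and transfer shuffles use seeds derived from
#'   it.
#' @return a list with `experiment`, `sessions` (list of two
#'   [build_learning_session()] results) and `transfer`
#'   ([build_transfer_schedule()] result).
#' @export
build_subject_schedules <- function(experiment, seed) {
  sessions <- lapply(1:2, function(s) build_learning_session(experiment, s, seed + s))
  ctx2 <- sessions[[2]]$contexts
  opts <- c(rbind(ctx2$favorable_option, ctx2$unfavorable_option))
  list(experiment = experiment, sessions = sessions,
       transfer = build_transfer_schedule(opts, seed + 3L))
}

# Pre-realize each option's outcome sequence over its 20 context
# presentations. "bernoulli" draws i.i.d.; "exact" fixes the non-zero count
# at p * 20 (15 or 5) and shuffles the order.
realize_outcomes <- function(contexts, mode = c("bernoulli", "exact")) {
  mode <- match.arg(mode)
  out <- list()
  for (i in seq_len(nrow(contexts))) {
    ct <- contexts[i, ]
    for (col in c("favorable", "unfavorable")) {
      opt <- ct[[paste0(col, "_option")]]
      p <- ct[[paste0("p_nonzero_", col)]]
      nz <- if (mode == "exact") {
        sample(rep(c(TRUE, FALSE), c(round(20 * p), 20 - round(20 * p))))
      } else {
        rbinom(20, 1, p) == 1
      }
      out[[opt]] <- ifelse(nz, ct$outcome_value, 0)
    }
  }
  out
}

#' Simulate an artificial subject performing the task
#'
#' Generative mode of the learning engine: on each learning trial the choice
#' is sampled from the model's choice probability, outcomes are drawn from
#' the option's outcome schedule, and values are updated exactly as in
#' [replay_likelihood()]. Transfer choices are sampled from the frozen
#' post-learning values; no outcomes are delivered in the transfer phase.
#'
#' @param params a [model_params()] object.
#' @param schedules a [build_subject_schedules()] result.
#' @param seed integer seed for choices and outcomes.
#' @param subject_id identifier written into the output tables.
#' @param outcome_mode `"bernoulli"` (independent draws per presentation) or
#'   `"exact"` (exactly 15/5 non-zero outcomes per 20 presentations).
#' @return a list with `learning` and `transfer` tibbles in the package's
#'   CSV schema (see [read_learning_trials()]).
#' @export
simulate_agent <- function(params, schedules, seed, subject_id = "s01",
                           outcome_mode = c("bernoulli", "exact")) {
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(inherits(params, "model_params"))
  experiment <- schedules$experiment
  any_complete <- any(vapply(schedules$sessions,
                             function(s) any(s$contexts$information == "complete"),
                             logical(1)))
  pc <- params_for_core(params, any_complete)
  model <- params$model

  with_seed(seed, {
    Q <- new.env(parent = emptyenv())
    V <- new.env(parent = emptyenv())
    rows <- vector("list", length(schedules$sessions))

    for (s_idx in seq_along(schedules$sessions)) {
      sess <- schedules$sessions[[s_idx]]
      ctxs <- sess$contexts
      outcomes <- realize_outcomes(ctxs, outcome_mode)
      seen <- stats::setNames(integer(nrow(ctxs)), ctxs$context_id)
      for (o in c(ctxs$favorable_option, ctxs$unfavorable_option)) assign(o, 0, envir = Q)
      for (cid in ctxs$context_id) assign(cid, 0, envir = V)

      slots <- sess$slots
      n <- nrow(slots)
      choice <- character(n); out_ch <- numeric(n); out_un <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        cid <- slots$context_id[i]
        ct <- ctxs[match(cid, ctxs$context_id), ]
        ol <- slots$option_left[i]; or <- slots$option_right[i]
        p_left <- choice_prob(model, get(ol, envir = Q), get(or, envir = Q), pc$beta)
        take_left <- runif(1) < p_left
        choice[i] <- if (take_left) "left" else "right"
        ch <- if (take_left) ol else or
        un <- if (take_left) or else ol

        k <- seen[[cid]] + 1L
        seen[[cid]] <- k
        out_ch[i] <- outcomes[[ch]][k]
        complete <- ct$information == "complete"
        if (complete) out_un[i] <- outcomes[[un]][k]

        v <- update_state_value(get(cid, envir = V), out_ch[i])
        if (complete) v <- update_state_value(v, out_un[i])
        assign(cid, v, envir = V)

        rc <- encode_outcome(model, out_ch[i], v, pc$omega, pc$upsilon)
        assign(ch, q_update(get(ch, envir = Q), rc, pc$alpha_f), envir = Q)
        if (complete) {
          ru <- encode_outcome(model, out_un[i], v, pc$omega, pc$upsilon)
          assign(un, q_update(get(un, envir = Q), ru, pc$alpha_c), envir = Q)
        }
      }

      info <- ctxs$information[match(slots$context_id, ctxs$context_id)]
      rows[[s_idx]] <- tibble::tibble(
        subject_id = subject_id, experiment = experiment,
        session = s_idx, trial = slots$trial,
        context_id = slots$context_id,
        valence = ctxs$valence[match(slots$context_id, ctxs$context_id)],
        magnitude = ctxs$magnitude[match(slots$context_id, ctxs$context_id)],
        information = info,
        option_left = slots$option_left, option_right = slots$option_right,
        choice = choice, outcome_chosen = out_ch, outcome_unchosen = out_un
      )
    }

    tsched <- schedules$transfer
    p_a <- vapply(seq_len(nrow(tsched)), function(i) {
      choice_prob(model, get(tsched$option_a[i], envir = Q),
                  get(tsched$option_b[i], envir = Q), pc$beta)
    }, numeric(1))
    transfer <- tibble::tibble(
      subject_id = subject_id, trial = tsched$trial,
      option_a = tsched$option_a, option_b = tsched$option_b,
      choice = ifelse(runif(nrow(tsched)) < p_a, "a", "b")
    )

    list(learning = dplyr::bind_rows(rows), transfer = transfer)
  })
}
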