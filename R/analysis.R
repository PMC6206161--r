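
chosen_option <- function(learning) {
  ifelse(learning$choice == "left", learning$option_left, learning$option_right)
}

#' Correct choice rate in the learning sessions
#'
#' Fraction of trials on which the favorable option — highest expected
#' reward, or lowest expected loss — was chosen, per subject and per
#' grouping factor. Chance level is 0.5.
#'
#' @param learning learning trials (any number of subjects).
#' @param by character vector of grouping columns among `valence`,
#'   `magnitude`, `information`, `session`, `context_id`; empty for one
#'   overall rate per subject.
#' @return a tibble with `subject_id`, the grouping columns, `n_trials`
#'   and `rate`.
#' @export
correct_choice_rate <- function(learning, by = c("valence", "magnitude")) {
  stopifnot(nrow(learning) > 0)
  cat1 <- option_catalog(learning$experiment[1])
  fav <- cat1$favorable[match(chosen_option(learning), cat1$option)]
  if (anyNA(fav)) stop("unknown option identifiers in learning trials", call. = FALSE)
  learning$correct <- fav
  learning |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", by)))) |>
    dplyr::summarise(n_trials = dplyr::n(), rate = mean(.data$correct),
                     .groups = "drop")
}

#' Per-subject magnitude effect
#'
#' Difference between big-magnitude and small-magnitude contexts' correct
#' choice rates (big minus small), the signature behavioral effect that
#' distinguishes absolute from fully range-normalized outcome encoding:
#' an absolute learner performs better when more money is at stake, a fully
#' normalized one is insensitive to magnitude.
#'
#' @param rates output of [correct_choice_rate()] with `magnitude` among its
#'   grouping columns.
#' @return a tibble with `subject_id` and `magnitude_effect`.
#' @export
magnitude_effect <- function(rates) {
  if (!"magnitude" %in% names(rates))
    stop("`rates` must be grouped by magnitude", call. = FALSE)
  rates |>
    dplyr::group_by(.data$subject_id, big = .data$magnitude == 1.0) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "big", values_from = "rate",
                       names_prefix = "m") |>
    dplyr::transmute(subject_id = .data$subject_id,
                     magnitude_effect = .data$mTRUE - .data$mFALSE)
}

#' Transfer-test choice rates, per symbol and pairwise
#'
#' The per-symbol choice rate is the number of times an option was chosen
#' divided by the number of times it was presented (28 presentations per
#' option in the full design). The pairwise table gives, for every ordered
#' pair, the rate at which the row option was chosen over the column option;
#' it satisfies `rate(i over j) + rate(j over i) = 1`, and each symbol's
#' overall rate is the mean of its 7 pairwise rates.
#'
#' @param transfer transfer trials (any number of subjects).
#' @param experiment experiment the options belong to (defaults to 2-style
#'   option ids; only used to attach option metadata).
#' @return a list with `symbol` (tibble: `subject_id`, `option`, `n_presented`,
#'   `n_chosen`, `rate`, `ev`, `favorable`) and `pairwise` (tibble:
#'   `subject_id`, `option_row`, `option_col`, `n`, `rate`).
#' @export
transfer_choice_rates <- function(transfer, experiment = 2) {
  stopifnot(nrow(transfer) > 0)
  cat1 <- option_catalog(experiment)
  chosen <- ifelse(transfer$choice == "a", transfer$option_a, transfer$option_b)
  other <- ifelse(transfer$choice == "a", transfer$option_b, transfer$option_a)

  long <- tibble::tibble(
    subject_id = rep(transfer$subject_id, 2),
    option = c(transfer$option_a, transfer$option_b),
    chosen = c(chosen == transfer$option_a, chosen == transfer$option_b)
  )
  symbol <- long |>
    dplyr::group_by(.data$subject_id, .data$option) |>
    dplyr::summarise(n_presented = dplyr::n(), n_chosen = sum(.data$chosen),
                     rate = mean(.data$chosen), .groups = "drop")
  symbol$ev <- cat1$ev[match(symbol$option, cat1$option)]
  symbol$favorable <- cat1$favorable[match(symbol$option, cat1$option)]

  pairwise <- tibble::tibble(
    subject_id = rep(transfer$subject_id, 2),
    option_row = c(chosen, other),
    option_col = c(other, chosen),
    won = rep(c(TRUE, FALSE), each = nrow(transfer))
  ) |>
    dplyr::group_by(.data$subject_id, .data$option_row, .data$option_col) |>
    dplyr::summarise(n = dplyr::n(), rate = mean(.data$won), .groups = "drop")

  list(symbol = symbol, pairwise = pairwise)
}

#' Average pairwise choice-rate matrix
#'
#' @param pairwise the `pairwise` tibble from [transfer_choice_rates()].
#' @return an 8x8 matrix of mean choice rates (row chosen over column),
#'   `NA` on the diagonal, options ordered by decreasing expected value.
#' @export
pairwise_matrix <- function(pairwise) {
  opts <- sort(unique(c(pairwise$option_row, pairwise$option_col)))
  m <- matrix(NA_real_, length(opts), length(opts), dimnames = list(opts, opts))
  agg <- pairwise |>
    dplyr::group_by(.data$option_row, .data$option_col) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  m[cbind(agg$option_row, agg$option_col)] <- agg$rate
  m
}

#' Transfer-test correct choice rate (absolute expected value)
#'
#' In the transfer phase "correct" means choosing the option with the higher
#' absolute expected value, probability x signed magnitude (+0.75, +0.25,
#' +0.075, +0.025, -0.025, -0.075, -0.25, -0.75 for the eight options), not
#' the option that was favorable within its original context. The design
#' never ties expected values across a pair; an assertion guards this.
#'
#' @inheritParams transfer_choice_rates
#' @return a tibble with `subject_id`, `n_trials`, `rate`.
#' @export
transfer_correct_rate <- function(transfer, experiment = 2) {
  cat1 <- option_catalog(experiment)
  ev_a <- cat1$ev[match(transfer$option_a, cat1$option)]
  ev_b <- cat1$ev[match(transfer$option_b, cat1$option)]
  if (any(ev_a == ev_b)) stop("tied expected values in a transfer pair", call. = FALSE)
  correct <- ifelse(transfer$choice == "a", ev_a > ev_b, ev_b > ev_a)
  tibble::tibble(subject_id = transfer$subject_id, correct = correct) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_trials = dplyr::n(), rate = mean(.data$correct),
                     .groups = "drop")
}

replay_with_fit <- function(fit_row, learning, transfer = NULL) {
  params <- model_params(fit_row$model, beta = fit_row$beta,
                         alpha_f = fit_row$alpha_f, alpha_c = fit_row$alpha_c,
                         omega = fit_row$omega, upsilon = fit_row$upsilon)
  replay_likelihood(params, learning, transfer)
}

#' Trial-wise model evidence: RELATIVE minus ABSOLUTE log-likelihood
#'
#' For every subject, replays the learning history under the subject's
#' fitted RELATIVE and fitted ABSOLUTE parameters and computes the per-trial
#' log-likelihood difference `log p_REL - log p_ABS` (positive means the
#' RELATIVE model explains that choice better). Differences are averaged
#' across the two sessions at each within-session trial index (1..80), then
#' summarized across subjects with an uncorrected t-test against 0 per
#' trial, and split into first-half (1-40) versus second-half (41-80) means
#' — relative value encoding is expected to emerge with learning, not to be
#' present from the first trials.
#'
#' @param learning learning trials of all subjects.
#' @param fits a [fit_cohort()] table containing an `ABSOLUTE` and a
#'   `RELATIVE` row per subject (typically `scope = "learning_only"`).
#' @return a list with `curve` (tibble: `trial`, `mean`, `sem`, `t`, `p`,
#'   `significant` at uncorrected alpha = 0.05), `halves` (tibble:
#'   `subject_id`, `first_half`, `second_half`), `halves_test` (paired
#'   t-test of second vs first half) and `subject_totals` (tibble:
#'   `subject_id`, `total_diff`, `nll_absolute`, `nll_relative`; the total
#'   satisfies `total_diff = nll_ABS - nll_REL`).
#' @export
trialwise_evidence <- function(learning, fits) {
  subjects <- unique(learning$subject_id)
  need <- c("ABSOLUTE", "RELATIVE")
  per_subj <- vector("list", length(subjects))
  totals <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    ls <- learning[learning$subject_id == sid, , drop = FALSE]
    rep_i <- lapply(need, function(m) {
      row <- fits[fits$subject_id == sid & fits$model == m, , drop = FALSE]
      if (nrow(row) != 1) stop("need exactly one ", m, " fit for subject ", sid, call. = FALSE)
      replay_with_fit(row[1, ], ls)
    })
    d <- rep_i[[2]]$traces$log_p - rep_i[[1]]$traces$log_p
    per_subj[[i]] <- tibble::tibble(subject_id = sid,
                                    trial = rep_i[[1]]$traces$trial, diff = d) |>
      dplyr::group_by(.data$subject_id, .data$trial) |>
      dplyr::summarise(diff = mean(.data$diff), .groups = "drop")
    totals[[i]] <- tibble::tibble(
      subject_id = sid, total_diff = sum(d),
      nll_absolute = rep_i[[1]]$nll_learning, nll_relative = rep_i[[2]]$nll_learning)
  }
  per_subj <- dplyr::bind_rows(per_subj)

  curve <- per_subj |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      mean = mean(.data$diff),
      sem = sd(.data$diff) / sqrt(dplyr::n()),
      t = tryCatch(t.test(.data$diff)$statistic, error = function(e) NA_real_),
      p = tryCatch(t.test(.data$diff)$p.value, error = function(e) NA_real_),
      .groups = "drop")
  curve$significant <- !is.na(curve$p) & curve$p < 0.05

  halves <- per_subj |>
    dplyr::group_by(.data$subject_id, half = ifelse(.data$trial <= 40, "first_half", "second_half")) |>
    dplyr::summarise(diff = mean(.data$diff), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "diff")
  halves_test <- tryCatch(
    t.test(halves$second_half, halves$first_half, paired = TRUE),
    error = function(e) NULL)

  list(curve = curve, halves = halves, halves_test = halves_test,
       subject_totals = dplyr::bind_rows(totals))
}

#' Posterior-predictive (one-step-ahead) choice probabilities
#'
#' Replays each subject's actual history of choices and outcomes under one
#' model's best-fitting parameters and extracts, for every learning trial,
#' the model's predicted probability of choosing the favorable option, and
#' for the transfer phase the predicted per-symbol choice rates implied by
#' the frozen post-learning values. Comparing these predictions with the
#' observed rates is the simulation-based falsification device: a model can
#' fit choices acceptably yet predict a behavioral pattern (e.g. a magnitude
#' effect) that the data do not show, or miss one they do.
#'
#' @param fits [fit_cohort()] rows for a single model.
#' @param learning learning trials of the same subjects.
#' @param transfer transfer trials, or `NULL` to skip transfer predictions.
#' @return a list with `learning_pred` (tibble: `subject_id`, `valence`,
#'   `magnitude`, `rate` — predicted correct-choice rates in the same shape
#'   as [correct_choice_rate()]), and `transfer_pred` (tibble: `subject_id`,
#'   `option`, `rate` — predicted per-symbol transfer choice rates), plus
#'   `model`.
#' @export
posterior_predictive <- function(fits, learning, transfer = NULL) {
  model <- unique(fits$model)
  if (length(model) != 1) stop("`fits` must contain a single model", call. = FALSE)
  cat1 <- option_catalog(learning$experiment[1])
  subjects <- unique(learning$subject_id)
  lp <- vector("list", length(subjects)); tp <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    ls <- learning[learning$subject_id == sid, , drop = FALSE]
    ts <- if (!is.null(transfer)) transfer[transfer$subject_id == sid, , drop = FALSE]
    row <- fits[fits$subject_id == sid, , drop = FALSE]
    if (nrow(row) != 1) stop("need exactly one fit row for subject ", sid, call. = FALSE)
    rp <- replay_with_fit(row[1, ], ls, ts)

    trc <- rp$traces
    fav_chosen <- cat1$favorable[match(trc$option_chosen, cat1$option)]
    p_correct <- ifelse(fav_chosen, trc$p_choice, 1 - trc$p_choice)
    meta <- ls[order(ls$session, ls$trial), c("valence", "magnitude")]
    lp[[i]] <- tibble::tibble(subject_id = sid, valence = meta$valence,
                              magnitude = meta$magnitude, p_correct = p_correct) |>
      dplyr::group_by(.data$subject_id, .data$valence, .data$magnitude) |>
      dplyr::summarise(rate = mean(.data$p_correct), .groups = "drop")

    if (!is.null(ts) && nrow(ts) > 0) {
      ttr <- rp$transfer_traces
      tp[[i]] <- tibble::tibble(
        subject_id = sid,
        option = c(ttr$option_chosen, ttr$option_other),
        p = c(ttr$p_choice, 1 - ttr$p_choice)
      ) |>
        dplyr::group_by(.data$subject_id, .data$option) |>
        dplyr::summarise(rate = mean(.data$p), .groups = "drop")
    }
  }
  list(model = model,
       learning_pred = dplyr::bind_rows(lp),
       transfer_pred = dplyr::bind_rows(tp))
}

#' Parameter-recovery summary for a synthetic cohort
#'
#' Joins the generating (true) parameters with the recovered (fitted) ones
#' and reports, for each parameter the generating model uses, the Pearson
#' correlation, mean bias (fit minus truth) and RMSE.
#'
#' @param ground_truth the `ground_truth` tibble of [generate_cohort()].
#' @param fits [fit_cohort()] rows for the generating model (one per
#'   subject).
#' @return a tibble with `parameter`, `n`, `r`, `p`, `bias`, `rmse`.
#' @export
parameter_recovery_report <- function(ground_truth, fits) {
  merged <- dplyr::inner_join(ground_truth, fits, by = "subject_id",
                              suffix = c("_true", "_fit"))
  if (nrow(merged) != nrow(ground_truth))
    stop("subject sets of ground truth and fits do not match", call. = FALSE)
  out <- list()
  for (p in c("beta", "alpha_f", "alpha_c", "omega", "upsilon")) {
    x <- merged[[paste0(p, "_true")]]; y <- merged[[paste0(p, "_fit")]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    ct <- suppressWarnings(cor.test(x[ok], y[ok]))
    out[[p]] <- tibble::tibble(parameter = p, n = sum(ok),
                               r = unname(ct$estimate), p = ct$p.value,
                               bias = mean(y[ok] - x[ok]),
                               rmse = sqrt(mean((y[ok] - x[ok])^2)))
  }
  dplyr::bind_rows(out)
}

#' Model-recovery confusion matrix
#'
#' For each subject, selects the model with the lowest BIC among the fitted
#' candidates and cross-tabulates generating model against selected model.
#' Rows sum to the number of subjects generated by each model.
#'
#' @param ground_truth the `ground_truth` tibble of [generate_cohort()].
#' @param fits [fit_cohort()] rows covering several candidate models.
#' @return a contingency table (generating model x BIC-selected model).
#' @export
model_confusion <- function(ground_truth, fits) {
  sel <- fits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_min(.data$bic, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", selected = "model")
  merged <- dplyr::inner_join(ground_truth[, c("subject_id", "model")], sel,
                              by = "subject_id")
  table(generating = merged$model, selected = merged$selected)
}

#' Correlation between the normalization weight and behavior
#'
#' Tests, across subjects, whether the HYBRID weight `omega` correlates (a)
#' positively with small-magnitude learning accuracy — normalization rescales
#' small outcomes so stronger normalizers learn small-stake contexts better —
#' and (b) negatively with transfer accuracy defined on absolute expected
#' value, where context-dependent values mislead.
#'
#' @param fits HYBRID [fit_cohort()] rows (one per subject, with `omega`).
#' @param learning,transfer the cohort's trial tables.
#' @return a tibble with `measure`, `n`, `r`, `r_squared`, `p`; `r` is `NA`
#'   (with a warning) if either variable is degenerate.
#' @export
omega_behavior_correlation <- function(fits, learning, transfer) {
  stopifnot(all(fits$model == "HYBRID"))
  small <- correct_choice_rate(learning, by = "magnitude") |>
    dplyr::filter(.data$magnitude == 0.1) |>
    dplyr::select("subject_id", small_rate = "rate")
  tcr <- transfer_correct_rate(transfer) |>
    dplyr::select("subject_id", transfer_rate = "rate")
  merged <- fits[, c("subject_id", "omega")] |>
    dplyr::inner_join(small, by = "subject_id") |>
    dplyr::inner_join(tcr, by = "subject_id")

  one <- function(y, name) {
    if (sd(merged$omega) == 0 || sd(y) == 0) {
      warning("degenerate variance; correlation with ", name, " undefined")
      return(tibble::tibble(measure = name, n = nrow(merged), r = NA_real_,
                            r_squared = NA_real_, p = NA_real_))
    }
    ct <- cor.test(merged$omega, y)
    tibble::tibble(measure = name, n = nrow(merged), r = unname(ct$estimate),
                   r_squared = unname(ct$estimate)^2, p = ct$p.value)
  }
  dplyr::bind_rows(one(merged$small_rate, "small_magnitude_learning"),
                   one(merged$transfer_rate, "transfer_absolute_value"))
}
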