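
# The four choice contexts of one learning session: the 2 x 2 factorial of
# outcome valence (reward / loss) and magnitude (1.0 EUR / 0.1 EUR).
CONTEXT_CODES <- tibble::tibble(
  code      = c("RB", "RS", "LB", "LS"),
  valence   = c("reward", "reward", "loss", "loss"),
  magnitude = c(1.0, 0.1, 1.0, 0.1)
)

# Complete-feedback contexts in Experiment 2, per session. Chosen so all
# eight valence x magnitude x information cells occur exactly once over the
# two sessions (the information factor is context-level; 2 partial + 2
# complete contexts per session = 50% of trials).
COMPLETE_BY_SESSION <- list(`1` = c("RB", "LS"), `2` = c("RS", "LB"))

#' Context specifications for one learning session
#'
#' Each session presents four novel fixed pairs of options ("contexts"):
#' reward/big, reward/small, loss/big, loss/small. Within a pair, the
#' favorable and unfavorable options carry reciprocal probabilities
#' (0.75/0.25) of the non-zero outcome: in reward contexts the favorable
#' option pays +M with probability 0.75; in loss contexts the favorable
#' option loses -M with probability only 0.25.
#'
#' In Experiment 1 all contexts give partial feedback (chosen outcome only).
#' In Experiment 2 two contexts per session also display the forgone
#' (counterfactual) outcome, so that complete-feedback trials make up 50% of
#' the session.
#'
#' @param experiment 1 or 2.
#' @param session_index 1 or 2.
#' @return a tibble with one row per context: `context_id`, `session`,
#'   `valence`, `magnitude` (EUR), `information` ("partial"/"complete"),
#'   `favorable_option`, `unfavorable_option`, `p_nonzero_favorable`,
#'   `p_nonzero_unfavorable`, and `outcome_value` (the signed non-zero
#'   outcome +M or -M).
#' @export
context_specs <- function(experiment, session_index) {
  check_exp_session(experiment, session_index)
  complete <- if (experiment == 2) COMPLETE_BY_SESSION[[as.character(session_index)]] else character()
  out <- CONTEXT_CODES
  out$session <- as.integer(session_index)
  out$context_id <- sprintf("s%d_%s", session_index, out$code)
  out$information <- ifelse(out$code %in% complete, "complete", "partial")
  out$favorable_option <- paste0(out$context_id, "_f")
  out$unfavorable_option <- paste0(out$context_id, "_u")
  out$p_nonzero_favorable <- ifelse(out$valence == "reward", 0.75, 0.25)
  out$p_nonzero_unfavorable <- 1 - out$p_nonzero_favorable
  out$outcome_value <- ifelse(out$valence == "reward", out$magnitude, -out$magnitude)
  out[, c("context_id", "session", "valence", "magnitude", "information",
          "favorable_option", "unfavorable_option",
          "p_nonzero_favorable", "p_nonzero_unfavorable", "outcome_value")]
}

check_exp_session <- function(experiment, session_index) {
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2", call. = FALSE)
  if (!session_index %in% c(1, 2)) stop("`session_index` must be 1 or 2", call. = FALSE)
  invisible(TRUE)
}

#' Catalog of all 16 options of an experiment
#'
#' One row per option across both sessions, with its context attributes, its
#' non-zero outcome probability and its expected value
#' (probability x signed magnitude). The transfer test involves only the 8
#' options of session 2.
#'
#' @param experiment 1 or 2.
#' @return a tibble with columns `option`, `context_id`, `session`,
#'   `valence`, `magnitude`, `information`, `favorable`, `p_nonzero`,
#'   `outcome_value`, `ev`.
#' @export
option_catalog <- function(experiment) {
  ctx <- dplyr::bind_rows(context_specs(experiment, 1), context_specs(experiment, 2))
  fav <- ctx
  fav$option <- fav$favorable_option
  fav$favorable <- TRUE
  fav$p_nonzero <- fav$p_nonzero_favorable
  unf <- ctx
  unf$option <- unf$unfavorable_option
  unf$favorable <- FALSE
  unf$p_nonzero <- unf$p_nonzero_unfavorable
  out <- dplyr::bind_rows(fav, unf)
  out$ev <- out$p_nonzero * out$outcome_value
  out <- out[order(out$session, out$context_id, -out$favorable), ]
  tibble::as_tibble(out[, c("option", "context_id", "session", "valence", "magnitude",
                            "information", "favorable", "p_nonzero",
                            "outcome_value", "ev")])
}

#' Build the pseudo-randomized trial schedule of one learning session
#'
#' Produces the four context specifications and an ordered list of 80 trial
#' slots (20 per context) in which no context repeats more than three times
#' consecutively, and each option appears on the left for exactly 10 of its
#' 20 presentations (side counterbalancing).
#'
#' @param experiment 1 or 2.
#' @param session_index 1 or 2.
#' @param seed integer; the schedule is reproducible bit-for-bit given
#'   `(experiment, session_index, seed)`.
#' @return a list with `contexts` (see [context_specs()]) and `slots`, a
#'   tibble with columns `trial` (1..80), `context_id`, `option_left`,
#'   `option_right`.
#' @export
build_learning_session <- function(experiment, session_index, seed) {
  check_exp_session(experiment, session_index)
  contexts <- context_specs(experiment, session_index)
  with_seed(seed, {
    ord <- interleave_contexts(nrow(contexts), 20L, max_run = 3L)
    slots <- tibble::tibble(
      trial = seq_along(ord),
      context_id = contexts$context_id[ord]
    )
    # favorable option on the left for exactly half of each context's trials
    slots$option_left <- NA_character_
    slots$option_right <- NA_character_
    for (i in seq_len(nrow(contexts))) {
      rows <- which(ord == i)
      fav_left <- sample(rep(c(TRUE, FALSE), length(rows) / 2))
      slots$option_left[rows] <- ifelse(fav_left, contexts$favorable_option[i],
                                        contexts$unfavorable_option[i])
      slots$option_right[rows] <- ifelse(fav_left, contexts$unfavorable_option[i],
                                         contexts$favorable_option[i])
    }
    list(contexts = contexts, slots = slots)
  })
}

# Random permutation of n_ctx contexts x n_rep repetitions with no run of a
# single context longer than max_run (rejection sampling; acceptance is fast
# for 4 contexts and a run bound of 3).
interleave_contexts <- function(n_ctx, n_rep, max_run = 3L) {
  base <- rep(seq_len(n_ctx), each = n_rep)
  repeat {
    ord <- sample(base)
    if (max(rle(ord)$lengths) <= max_run) return(ord)
  }
}

#' Build the feedback-free transfer-test schedule
#'
#' The 8 options of the final learning session are presented in all 28
#' distinct unordered pairs, each pair 4 times (112 trials), in shuffled
#' order. Within each pair, each option takes the left slot (`option_a`)
#' exactly twice.
#'
#' @param options character vector of exactly 8 distinct option identifiers.
#' @param seed integer RNG seed for the shuffle.
#' @return a tibble with columns `trial` (1..112), `option_a`, `option_b`.
#' @export
build_transfer_schedule <- function(options, seed) {
  if (length(options) != 8L) stop("transfer test requires exactly 8 options", call. = FALSE)
  if (anyDuplicated(options)) stop("duplicate option identifiers", call. = FALSE)
  pairs <- t(combn(options, 2L))
  a <- c(pairs[, 1], pairs[, 1], pairs[, 2], pairs[, 2])
  b <- c(pairs[, 2], pairs[, 2], pairs[, 1], pairs[, 1])
  with_seed(seed, {
    ord <- sample(length(a))
    tibble::tibble(trial = seq_along(ord), option_a = a[ord], option_b = b[ord])
  })
}

#' Sample one probabilistic outcome for an option
#'
#' Draws the option's non-zero outcome (+M in reward contexts, -M in loss
#' contexts) with its design probability, and 0 otherwise. Uses the current
#' RNG state; wrap in [set.seed()] for reproducibility.
#'
#' @param option option identifier; must belong to `context`.
#' @param context a single-row context specification (one row of
#'   [context_specs()]).
#' @param n number of independent draws.
#' @return numeric vector of outcomes in EUR.
#' @export
sample_outcome <- function(option, context, n = 1L) {
  stopifnot(nrow(context) == 1L)
  p <- if (option == context$favorable_option) {
    context$p_nonzero_favorable
  } else if (option == context$unfavorable_option) {
    context$p_nonzero_unfavorable
  } else {
    stop(sprintf("option '%s' does not belong to context '%s'", option, context$context_id),
         call. = FALSE)
  }
  rbinom(n, 1L, p) * context$outcome_value
}
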