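
OUTCOME_ALPHABET <- c(-1.0, -0.1, 0.0, 0.1, 1.0)

#' Construct and validate a model parameter set
#'
#' The five models share a softmax temperature `beta` and a factual learning
#' rate `alpha_f`; `alpha_c` is the counterfactual learning rate applied to
#' the forgone outcome on complete-feedback trials (Experiment 2 data only);
#' `omega` is the HYBRID model's weight on the relative (context-normalized)
#' encoding; `upsilon` is the UTILITY model's multiplicative scaling of
#' big-magnitude outcomes.
#'
#' @param model one of `r paste(MODEL_NAMES, collapse = ", ")`.
#' @param beta softmax temperature, > 0.
#' @param alpha_f factual learning rate in \[0, 1\].
#' @param alpha_c counterfactual learning rate in \[0, 1\], or `NA` for
#'   partial-feedback-only (Experiment 1) data.
#' @param omega HYBRID weight in \[0, 1\] (`NA` for other models).
#' @param upsilon UTILITY scaling in \[0.1, 1.0\] (`NA` for other models).
#' @return a list of class `model_params`.
#' @export
model_params <- function(model, beta, alpha_f, alpha_c = NA_real_,
                         omega = NA_real_, upsilon = NA_real_) {
  model <- match.arg(model, MODEL_NAMES)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  check_unit <- function(x, nm) {
    if (!is.na(x) && (x < 0 || x > 1)) stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  check_unit(alpha_f, "alpha_f")
  check_unit(alpha_c, "alpha_c")
  if (model == "HYBRID") {
    if (is.na(omega)) stop("HYBRID requires omega", call. = FALSE)
    check_unit(omega, "omega")
  }
  if (model == "UTILITY") {
    if (is.na(upsilon) || upsilon < 0.1 || upsilon > 1.0)
      stop("UTILITY requires upsilon in [0.1, 1.0]", call. = FALSE)
  }
  structure(list(model = model, beta = beta, alpha_f = alpha_f,
                 alpha_c = alpha_c, omega = omega, upsilon = upsilon),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  pars <- unlist(x[c("beta", "alpha_f", "alpha_c", "omega", "upsilon")])
  pars <- pars[!is.na(pars)]
  cat(x$model, "model:", paste(names(pars), signif(pars, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Absolute outcome encoding
#'
#' Outcomes enter the delta rule at their face monetary value. This is the
#' identity on the task's outcome alphabet \{-1.0, -0.1, 0, +0.1, +1.0\} EUR;
#' values outside the alphabet are passed through with a warning.
#'
#' @param outcome numeric outcome(s) in EUR.
#' @return the encoded outcome(s), unchanged.
#' @export
encode_absolute <- function(outcome) {
  if (!all(outcome %in% OUTCOME_ALPHABET))
    warning("outcome outside the task alphabet; passed through unchanged")
  outcome
}

#' Update a context's state value from an observed outcome
#'
#' The state value V(s) anchors the relative encoding. It starts at 0 and
#' takes the value of the first non-zero outcome observed in the context
#' (chosen or, on complete-feedback trials, unchosen), then stays frozen.
#'
#' @param v current state value (0 if not yet set).
#' @param outcome observed outcome in EUR.
#' @return the updated state value.
#' @export
update_state_value <- function(v, outcome) {
  if (v != 0) v else if (outcome != 0) outcome else 0
}

#' Relative (range + reference-point normalized) outcome encoding
#'
#' Divides the outcome by the magnitude of the context value |V(s)| (range
#' adaptation) and adds `max(0, -V(s)/|V(s)|)` (reference-point correction,
#' +1 in loss contexts). Once V(s) is set, every legal outcome of the
#' context maps to the binary correct/incorrect scale \{0, 1\}: in a loss
#' context an avoided loss (outcome 0) encodes as 1 — a relative reward —
#' and an incurred loss as 0. While V(s) is still 0 (no non-zero outcome
#' seen yet, so only zero outcomes can reach this branch) the encoding is
#' defined as 0.
#'
#' @param outcome outcome in EUR.
#' @param v state value of the option's context, already updated for the
#'   current trial (see [update_state_value()]).
#' @return the encoded outcome.
#' @export
encode_relative <- function(outcome, v) {
  if (v == 0) return(0)
  outcome / abs(v) + max(0, -v / abs(v))
}

#' Hybrid outcome encoding
#'
#' Convex combination `omega * relative + (1 - omega) * absolute`; reduces
#' to the ABSOLUTE encoding at `omega = 0` and the RELATIVE one at
#' `omega = 1`.
#'
#' @inheritParams encode_relative
#' @param omega weight on the relative encoding, in \[0, 1\].
#' @export
encode_hybrid <- function(outcome, v, omega) {
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]", call. = FALSE)
  omega * encode_relative(outcome, v) + (1 - omega) * encode_absolute(outcome)
}

#' Utility outcome encoding (marginally decreasing utility)
#'
#' Big-magnitude outcomes (|outcome| = 1.0 EUR) are rescaled by `upsilon`;
#' small-magnitude and zero outcomes are unchanged. At `upsilon = 1` the
#' model reduces to ABSOLUTE.
#'
#' @param outcome outcome in EUR.
#' @param upsilon multiplicative factor in \[0.1, 1.0\].
#' @export
encode_utility <- function(outcome, upsilon) {
  if (upsilon < 0.1 || upsilon > 1.0) stop("upsilon must lie in [0.1, 1.0]", call. = FALSE)
  ifelse(abs(abs(outcome) - 1) < 1e-9, upsilon * outcome, outcome)
}

# Overflow-safe logistic on exponent argument z: P = 1 / (1 + exp(z)).
safe_logistic <- function(z) 1 / (1 + exp(pmin(pmax(z, -500), 500)))

#' Softmax probability of choosing option a over option b
#'
#' `P(a) = 1 / (1 + exp((Q_b - Q_a) / beta))`. High temperatures make the
#' options near equi-probable; low temperatures make choice nearly
#' deterministic toward the higher value.
#'
#' @param q_a,q_b option values.
#' @param beta temperature, > 0.
#' @return probability of choosing `a`; `P(a) + P(b) = 1` by construction.
#' @export
softmax_prob <- function(q_a, q_b, beta) {
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  safe_logistic((q_b - q_a) / beta)
}

#' Divisively normalized (POLICY) choice probability
#'
#' The POLICY model keeps absolute option values but normalizes the value
#' difference by the value sum inside the softmax:
#' `P(a) = 1 / (1 + exp(((Q_b - Q_a)/(Q_b + Q_a)) * (1/beta)))`.
#' When the denominator is numerically zero (|Q_a + Q_b| < 1e-12) the
#' normalized difference is taken as 0 and P(a) = 0.5. The formula is
#' otherwise applied literally, including negative denominators when both
#' values are negative (loss contexts), which flips the sign of the
#' normalized difference.
#'
#' @inheritParams softmax_prob
#' @export
policy_prob <- function(q_a, q_b, beta) {
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  den <- q_a + q_b
  z <- ifelse(abs(den) < 1e-12, 0, (q_b - q_a) / den / beta)
  safe_logistic(z)
}

#' Rescorla-Wagner (delta-rule) value update
#'
#' `Q <- Q + alpha * (R - Q)` where `R` is the encoded outcome. Applied to
#' the chosen option with the factual rate always, and to the unchosen
#' option with the counterfactual rate only when its outcome was displayed.
#'
#' @param q current value.
#' @param r_encoded encoded outcome.
#' @param alpha learning rate in \[0, 1\].
#' @export
q_update <- function(q, r_encoded, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  q + alpha * (r_encoded - q)
}

# Dispatch outcome encoding for a model given the (already updated) state
# value of the outcome's context. POLICY encodes absolutely; its
# normalization lives in the choice rule.
encode_outcome <- function(model, outcome, v, omega, upsilon) {
  switch(model,
    ABSOLUTE = ,
    POLICY   = outcome,
    RELATIVE = encode_relative(outcome, v),
    HYBRID   = omega * encode_relative(outcome, v) + (1 - omega) * outcome,
    UTILITY  = encode_utility(outcome, upsilon),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# Choice rule for a model: probability of choosing the option with value q_a.
choice_prob <- function(model, q_a, q_b, beta) {
  if (model == "POLICY") policy_prob(q_a, q_b, beta) else softmax_prob(q_a, q_b, beta)
}
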