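# Small seeded fixtures, generated in code at test time.

# One simulated subject with known parameters.
one_subject <- function(seed = 42, experiment = 2, model = "HYBRID",
                        params = NULL, id = "s01") {
  if (is.null(params)) {
    params <- model_params(
      model, beta = 0.15, alpha_f = 0.35,
      alpha_c = if (experiment == 2) 0.2 else NA_real_,
      omega = if (model == "HYBRID") 0.5 else NA_real_,
      upsilon = if (model == "UTILITY") 0.6 else NA_real_)
  }
  sched <- build_subject_schedules(experiment, seed)
  sim <- simulate_agent(params, sched, seed + 7L, subject_id = id)
  c(sim, list(params = params, schedules = sched))
}

# A compact synthetic cohort.
small_cohort <- function(seed = 1, n_exp1 = 0, n_exp2 = 4, model = "HYBRID",
                         priors = list()) {
  generate_cohort(cohort_config(n_exp1 = n_exp1, n_exp2 = n_exp2,
                                model = model, priors = priors, seed = seed))
}

# Per-trial choice probabilities of a replay, as a bare vector.
replay_p <- function(params, learning, transfer = NULL) {
  r <- replay_likelihood(params, learning, transfer)
  list(learning = r$traces$p_choice, transfer = r$transfer_traces$p_choice,
       nll = r$nll, r = r)
}
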