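# contextRL

Context-dependent reinforcement learning models for probabilistic bandit
tasks with a post-learning transfer test.

## The scientific problem

When people learn option values from monetary feedback, do they encode
outcomes on an *absolute* scale (euros) or *relative* to the local choice
context? The question has behavioral teeth: a learner who range-normalizes
outcomes learns a 10-cent context exactly as well as a 1-euro context, but
pays for it later, because context-free ("absolute") value comparisons
across contexts are then distorted.

`contextRL` implements the full computational pipeline for studying this
question in a fixed-pair instrumental learning task:

- **Task.** Two learning sessions of 80 trials. Each session interleaves
  four fixed option pairs ("contexts") crossing outcome valence
  (gain/loss) with magnitude (±1.0 € / ±0.1 €); within a pair the two
  options carry reciprocal probabilities (0.75/0.25) of the non-zero
  outcome. Experiment-2-style subjects additionally see the forgone
  outcome on half the trials (complete feedback). After learning, a
  feedback-free **transfer test** pairs the final session's 8 options in
  all 28 combinations, 4 times each (112 trials).
- **Models.** Five Q-learning variants sharing the Rescorla–Wagner update
  `Q ← Q + α(R − Q)` and a softmax choice rule
  `P(a) = 1/(1 + exp((Q_b − Q_a)/β))`, differing in outcome encoding:
  - `ABSOLUTE`: `R` is the outcome in euros.
  - `RELATIVE`: `R = R_abs/|V(s)| + max{0, −V(s)/|V(s)|}`, where the state
    value `V(s)` is the first non-zero outcome observed in context `s`
    (then frozen). Outcomes become binary correct/incorrect: an avoided
    loss encodes as a relative reward.
  - `HYBRID`: `R = ω·R_rel + (1 − ω)·R_abs`, with subject-level weight ω.
  - `UTILITY`: big-magnitude outcomes rescaled by `υ ∈ [0.1, 1]`
    (marginally decreasing utility).
  - `POLICY`: absolute values, divisive normalization
    `(Q_b − Q_a)/(Q_b + Q_a)` inside the softmax only.
- **Fitting.** Subject-level maximum likelihood (multi-start bounded
  L-BFGS-B) on three scopes — learning sessions (160 trials), transfer
  test (112), or both (272) — and model comparison by
  `BIC = 2·NLL + ln(ntrials)·df`.
- **Analyses.** Correct-choice rates and the magnitude effect
  (big-context minus small-context accuracy), transfer per-symbol and
  pairwise preference matrices, trial-wise RELATIVE-vs-ABSOLUTE model
  evidence, posterior-predictive (one-step-ahead) falsification of models
  against the behavioral patterns, and parameter/model recovery on
  synthetic cohorts with known ground truth.

## Worked example

Simulate a 10-subject Experiment-2-style cohort generated by the HYBRID
model, refit it, and look at recovery:

```r
library(contextRL)

cfg  <- cohort_config(n_exp1 = 0, n_exp2 = 10, model = "HYBRID", seed = 42)
coh  <- generate_cohort(cfg)
fits <- fit_cohort(coh$learning, coh$transfer, models = "HYBRID", scopes = "both")
parameter_recovery_report(coh$ground_truth, fits)
#> # A tibble: 4 × 6
#>   parameter     n     r            p      bias   rmse
#>   <chr>     <int> <dbl>        <dbl>     <dbl>  <dbl>
#> 1 beta         10 0.986 0.000000186  -0.000412 0.0377
#> 2 alpha_f      10 0.912 0.000231     -0.00558  0.0604
#> 3 alpha_c      10 0.810 0.00448      -0.0368   0.0802
#> 4 omega        10 0.990 0.0000000386  0.0106   0.0471
```

The correlations say the generating temperature, learning rates and
normalization weight are all recovered from 272 choices per subject; the
`bias` column (fit minus truth) shows no systematic distortion at this
cohort size.

Behavioral signature of normalization — the magnitude effect:

```r
me <- magnitude_effect(correct_choice_rate(coh$learning, by = "magnitude"))
mean(me$magnitude_effect)
#> [1] 0.0675
```

A cohort with intermediate weights (ω drawn uniformly) shows a small
positive effect: accuracy is a few points higher when 1 € rather than
0.1 € is at stake — more than a fully relative learner (no effect) and
less than a fully absolute one would produce.

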