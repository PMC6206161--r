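---
title: "Context-dependent value learning: models, fitting, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent value learning: models, fitting, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextRL)
```

## The task and what it isolates

The package models a probabilistic instrumental-learning task built around
*fixed option pairs*. Each learning session interleaves four pairs of
abstract cues; a pair always appears together, so it constitutes a stable
choice context with a well-defined local outcome range. The four contexts
cross outcome **valence** (gains vs. losses) with outcome **magnitude**
(±1.0 € vs. ±0.1 €); within a pair the favorable and unfavorable options
deliver the context's non-zero outcome with reciprocal probabilities
(0.75/0.25). A session has 80 trials (20 per context); subjects complete
two sessions with novel cues, and Experiment-2-style subjects also see the
forgone outcome in half of the contexts (complete feedback). Learning is
followed by a feedback-free **transfer test**: the last session's eight
options in all 28 binary combinations, four repetitions each.

The design separates two ways a learner can represent value. During
learning, all choices are *within* context, so context-normalized and
absolute value codes predict similar preferences. The transfer test forces
*between*-context comparisons, where the two codes dissociate sharply: a
normalized learner will, for example, prefer the favorable option of a
small-loss context over the unfavorable option of a big-reward context
even though the latter has the higher expected monetary value.

## The model space

All five models are delta-rule learners,
$Q \leftarrow Q + \alpha\,(R - Q)$, with a softmax policy
$P(a) = 1/(1 + e^{(Q_b - Q_a)/\beta})$, and differ only in how the
feedback $R$ enters the update (or, for one model, how values enter the
policy):

| Model | Outcome encoding | Extra parameter |
|---|---|---|
| `ABSOLUTE` | face value in euros | — |
| `RELATIVE` | $R_{abs}/|V(s)| + \max\{0, -V(s)/|V(s)|\}$ | — |
| `HYBRID` | $\omega R_{rel} + (1-\omega) R_{abs}$ | $\omega \in [0,1]$ |
| `UTILITY` | $\upsilon R_{abs}$ for big magnitudes only | $\upsilon \in [0.1,1]$ |
| `POLICY` | face value; softmax uses $(Q_b-Q_a)/(Q_b+Q_a)$ | — |

The RELATIVE encoding uses a **state value** $V(s)$ per context:
initialized at 0, set to the first non-zero outcome observed in that
context (chosen outcome inspected first, then the forgone one if
displayed), then frozen. Once $V(s)$ is set, division by $|V(s)|$ removes
the magnitude (range adaptation) and the $\max\{0, \cdot\}$ term recenters
loss contexts (reference-point correction), so every legal outcome maps to
a binary correct/incorrect code — an avoided loss literally becomes a
relative reward (encodes as 1).

On complete-feedback trials the forgone outcome is encoded the same way
and updates the unchosen option with its own **counterfactual learning
rate** $\alpha_C$; on partial-feedback trials (and all Experiment-1 data)
only the chosen option updates, with the factual rate $\alpha_F$.

### Parameters, units, defaults

- $\beta$ (temperature, same units as encoded outcomes): fitted in
  $[10^{-3}, 100]$. Cohort prior: log-normal, median 0.15, log-sd 0.5 —
  the magnitude at which a 0.5 € value difference is near-deterministic
  but a 0.05 € difference is not, which is the regime this task puts
  subjects in.
- $\alpha_F, \alpha_C \in [0,1]$: cohort priors Beta(2,4) (mean 1/3) and
  Beta(2,6); counterfactual learning is typically somewhat slower.
- $\omega \in [0,1]$: prior Uniform(0,1), a deliberately broad spread so
  recovery is probed over the whole normalization continuum.
- $\upsilon \in [0.1, 1]$: prior Uniform(0.1, 1).

## Decisions where the design was open

- **Q initialization** at 0 for every option, making every first encounter
  a 50/50 prediction.
- **V update ordering.** $V(s)$ is updated from the trial's observed
  outcomes *before* either outcome is encoded, so the very trial that
  first reveals a non-zero outcome already encodes it relatively. The
  alternative (encode first, then anchor) would delay normalization by one
  feedback event; the chosen reading treats the anchor as defining the
  context at evaluation time.
- **$V(s) = 0$ branch.** Before the context is anchored only zero outcomes
  can reach the relative encoder (a non-zero outcome would have anchored
  $V$ first); the encoding is defined as 0 there.
- **POLICY's denominator.** $(Q_b - Q_a)/(Q_b + Q_a)$ is applied
  literally. When both values are negative the denominator flips the sign
  of the normalized difference — a real property of this functional form,
  documented rather than patched. Only the numerically degenerate case
  $|Q_a + Q_b| < 10^{-12}$ is guarded, yielding $P = 0.5$.
- **Information factor in Experiment 2.** Feedback information is treated
  as a context-level factor: two partial and two complete contexts per
  session (50% of trials), counterbalanced across the two sessions so that
  all eight valence × magnitude × information cells occur exactly once per
  subject.
- **Pseudo-randomization.** Context order is a uniform shuffle constrained
  to at most 3 consecutive repeats of a context; each option appears on
  the left for exactly half of its 20 presentations.
- **Outcome realization.** Bernoulli draws per presentation by default; an
  `"exact"` mode fixes 15/5 non-zero outcomes per 20 presentations for
  users who prefer frequency-exact schedules.
- **Transfer phase.** Values are frozen (no feedback is delivered, so
  nothing updates), and the learning-phase $\beta$ and choice rule are
  reused; POLICY normalizes in transfer too.
- **BIC.** $\mathrm{BIC} = 2\,\mathrm{NLL} + \ln(n)\,df$ with the natural
  logarithm; $n$ is 160, 112 or 272 depending on the fitting scope, and
  $df$ counts only the parameters the data can constrain (no $\alpha_C$
  for partial-feedback-only subjects).
- **Transfer-only fitting** still replays the learning phase to build the
  values — transfer choices are meaningless otherwise — but sums only the
  112 transfer log-likelihoods.

## Numerical choices

- Choice probabilities use an overflow-safe logistic (exponent clipped to
  ±500) and are floored at $10^{-15}$ before logs, bounding any single
  trial's contribution to the NLL.
- Optimization: bounded L-BFGS-B from the conventional start
  ($\beta = 1$, rates and weights 0.5) plus nine deterministic
  low-discrepancy starts inside the box (temperature mapped through a
  log scale). Deterministic starts keep fits exactly reproducible without
  consuming RNG state. `factr = 1e7`, 500 iterations max.
- A brute-force grid search over the full parameter box is shipped as a
  reference optimizer; the test suite requires the local optimizer to
  reach the 11-points-per-axis grid optimum within 0.01 nats.
- The likelihood core exists twice on purpose: a pure-R replay that
  exposes every per-trial quantity (probabilities, encoded outcomes,
  prediction errors, value trajectories) and a compiled C++ fast path used
  inside optimization. The suite asserts agreement to $10^{-9}$ across all
  five models and all scopes, so the fast path never silently diverges
  from the documented semantics.

## What the synthetic cohorts do and do not emulate

`generate_cohort()` reproduces the *statistical skeleton* of the two
experiments: cohort sizes (20 partial-feedback-only, 40 with complete
feedback), schedule structure, outcome probabilities, and agents whose
parameters are drawn from the priors above, with per-subject seeds derived
by stable hashing so cohorts are extensible without reshuffling. It does
not emulate reaction times, missed responses, attention lapses, choice
perseveration, session-order effects, or any explicit memory of cue
identity — so green tests certify the pipeline (schedules, likelihoods,
optimizer, analyses) and the internal consistency of the model space, not
claims about human data. Analyses of real datasets require only the CSV
schema of `read_learning_trials()` / `read_transfer_trials()` plus a
column-mapping step from the source format.

Problem sizes used by the validation suite and the acceptance script —
40-subject cohorts for parameter recovery and falsification, 20-subject
cohorts for model recovery, ten 20-subject cohorts for the
weight-behavior sign tests — were chosen as the smallest sizes at which
the corresponding group-level statistics are conventionally powered, and
they match the real experiments' cohort sizes where one exists.

## Trial-wise evidence and falsification analyses

`trialwise_evidence()` computes, per subject and trial, the
log-likelihood difference between the fitted RELATIVE and ABSOLUTE models,
averaged across the two sessions at each within-session trial index
(1–80). Early trials — before $V(s)$ anchors and before values diverge
across contexts — carry no discriminative information, so relative value
encoding is expected to *emerge* over trials; the first-half vs.
second-half split quantifies that. Per-trial significance markers use
uncorrected t-tests at $\alpha = 0.05$; they are descriptive, and no
multiple-comparison correction is applied by design.

`posterior_predictive()` implements simulation-based falsification in its
one-step-ahead form: each subject's *actual* history drives the value
updates, and the model contributes only its choice probability per trial.
Comparing predicted and observed correct-choice rates per context exposes
models that fit choices acceptably yet imply the wrong behavioral
signature — the ABSOLUTE model over-predicts the magnitude effect of a
mixed-weight cohort and the RELATIVE model predicts essentially none,
while group statistics are replaced by paired t-tests on factor-level
means throughout (full repeated-measures ANOVA tables are outside this
package's scope).

## Known limitations

- The model space deliberately excludes perseveration terms, lapse rates,
  asymmetric valence learning rates and eligibility traces; none is needed
  to express the absolute-vs-relative question, but fits to rich real data
  may absorb such effects into $\beta$.
- The POLICY model's sign behavior for all-negative value pairs (above)
  makes its likelihood surface irregular in loss-heavy regimes;
  multi-start optimization mitigates but cannot fully remove the risk of
  local optima there.
- With $\alpha_C = 0$ a displayed forgone outcome still anchors $V(s)$:
  information display and counterfactual *learning* are distinct
  mechanisms, and only the latter is gated by $\alpha_C$. Equivalence with
  partial-feedback replay therefore holds exactly for the V-free models
  (ABSOLUTE, UTILITY, POLICY) and up to $V$-anchoring timing for the
  normalized ones.
- Transfer "correct" responses are defined by absolute expected value
  (probability × signed magnitude); the eight transfer options have
  pairwise-distinct expected values in this design, and the code asserts
  this rather than defining tie-breaking.
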