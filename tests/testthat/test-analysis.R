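
# force every learning choice toward (or away from) the favorable option
force_choices <- function(learning, correct = TRUE) {
  cat1 <- option_catalog(learning$experiment[1])
  fav_left <- cat1$favorable[match(learning$option_left, cat1$option)]
  learning$choice <- ifelse(fav_left == correct, "left", "right")
  learning
}

test_that("correct choice rate hits its deterministic extremes", {
  subj <- one_subject(seed = 70)
  always <- force_choices(subj$learning, correct = TRUE)
  never <- force_choices(subj$learning, correct = FALSE)
  expect_true(all(correct_choice_rate(always)$rate == 1))
  expect_true(all(correct_choice_rate(never)$rate == 0))
  by_ctx <- correct_choice_rate(always, by = "context_id")
  expect_equal(nrow(by_ctx), 8)
  expect_true(all(by_ctx$n_trials == 20))
})

test_that("magnitude effect is the big-minus-small rate difference", {
  subj <- one_subject(seed = 71)
  rates <- correct_choice_rate(force_choices(subj$learning), by = "magnitude")
  expect_equal(magnitude_effect(rates)$magnitude_effect, 0)  # 1 - 1
  # hand-built asymmetric table
  tab <- tibble::tibble(subject_id = "x", magnitude = c(1, 0.1), rate = c(0.8, 0.6))
  expect_equal(magnitude_effect(tab)$magnitude_effect, 0.2)
  expect_error(magnitude_effect(tab[, -2]), "magnitude")
})

test_that("transfer rates satisfy the complement and averaging identities", {
  coh <- small_cohort(seed = 72, n_exp2 = 3)
  tcr <- transfer_choice_rates(coh$transfer)
  expect_true(all(tcr$symbol$n_presented == 28))
  # complement: rate(i over j) + rate(j over i) = 1
  pw <- tcr$pairwise
  flip <- merge(pw, pw,
                by.x = c("subject_id", "option_row", "option_col"),
                by.y = c("subject_id", "option_col", "option_row"))
  expect_equal(flip$rate.x + flip$rate.y, rep(1, nrow(flip)))
  # per-symbol rate equals the mean of its 7 pairwise rates
  agg <- aggregate(rate ~ subject_id + option_row, pw, mean)
  m <- merge(tcr$symbol, agg, by.x = c("subject_id", "option"),
             by.y = c("subject_id", "option_row"))
  expect_equal(m$rate.x, m$rate.y)

  mat <- pairwise_matrix(pw)
  expect_equal(dim(mat), c(8, 8))
  expect_true(all(is.na(diag(mat))))
  off <- !is.na(mat)
  expect_equal(mat[off] + t(mat)[off], rep(1, sum(off)))
})

test_that("transfer correct rate follows absolute expected value", {
  coh <- small_cohort(seed = 73, n_exp2 = 2)
  tt <- coh$transfer
  cat2 <- option_catalog(2)
  ev_a <- cat2$ev[match(tt$option_a, cat2$option)]
  ev_b <- cat2$ev[match(tt$option_b, cat2$option)]
  tt$choice <- ifelse(ev_a > ev_b, "a", "b")
  expect_true(all(transfer_correct_rate(tt)$rate == 1))
  tt$choice <- ifelse(ev_a > ev_b, "b", "a")
  expect_true(all(transfer_correct_rate(tt)$rate == 0))
})

test_that("trial-wise evidence sums to the model nll difference and spans 80 trials", {
  coh <- small_cohort(seed = 74, n_exp2 = 3)
  fits <- fit_cohort(coh$learning, NULL, models = c("ABSOLUTE", "RELATIVE"),
                     scopes = "learning_only", n_starts = 3)
  ev <- trialwise_evidence(coh$learning, fits)
  expect_equal(nrow(ev$curve), 80)
  expect_true(all(c("mean", "sem", "t", "p", "significant") %in% names(ev$curve)))
  # additivity: per-subject total diff = NLL(ABS) - NLL(REL)
  expect_lt(max(abs(ev$subject_totals$total_diff -
                      (ev$subject_totals$nll_absolute - ev$subject_totals$nll_relative))),
            1e-9)
  expect_equal(nrow(ev$halves), 3)
})

test_that("posterior-predictive probabilities are proper and shaped like observed rates", {
  coh <- small_cohort(seed = 75, n_exp2 = 2)
  fits <- fit_cohort(coh$learning, coh$transfer, models = "HYBRID",
                     scopes = "both", n_starts = 3)
  pp <- posterior_predictive(fits, coh$learning, coh$transfer)
  expect_setequal(names(pp$learning_pred),
                  c("subject_id", "valence", "magnitude", "rate"))
  expect_true(all(pp$learning_pred$rate > 0 & pp$learning_pred$rate < 1))
  expect_true(all(pp$transfer_pred$rate > 0 & pp$transfer_pred$rate < 1))
  expect_equal(nrow(pp$transfer_pred), 2 * 8)
  # mixing two models in one fits table is rejected
  fits2 <- fit_cohort(coh$learning, coh$transfer, models = c("ABSOLUTE", "RELATIVE"),
                      scopes = "both", n_starts = 2)
  expect_error(posterior_predictive(fits2, coh$learning), "single model")
})

test_that("recovery reports join truth to fits and confusion rows sum to cohort sizes", {
  coh <- small_cohort(seed = 76, n_exp2 = 4)
  fits <- fit_cohort(coh$learning, coh$transfer, models = "HYBRID",
                     scopes = "both", n_starts = 3)
  rec <- parameter_recovery_report(coh$ground_truth, fits)
  expect_setequal(rec$parameter, c("beta", "alpha_f", "alpha_c", "omega"))
  expect_true(all(rec$n == 4))
  expect_true(all(is.finite(rec$rmse)))

  fits_both <- fit_cohort(coh$learning, coh$transfer,
                          models = c("ABSOLUTE", "HYBRID"), scopes = "both",
                          n_starts = 3)
  cm <- model_confusion(coh$ground_truth, fits_both)
  expect_equal(sum(cm), 4)
  expect_equal(unname(rowSums(cm)[["HYBRID"]]), 4)
})

test_that("omega-behavior correlation flags degenerate cohorts", {
  coh <- small_cohort(seed = 77, n_exp2 = 3,
                      priors = list(omega = list(dist = "fixed", value = 0.5)))
  fits <- fit_cohort(coh$learning, coh$transfer, models = "HYBRID",
                     scopes = "both", n_starts = 2)
  fits$omega <- 0.5  # exactly constant
  w <- testthat::capture_warnings(
    out <- omega_behavior_correlation(fits, coh$learning, coh$transfer))
  expect_length(w, 2)
  expect_match(w, "degenerate", all = TRUE)
  expect_true(all(is.na(out$r)))
})
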