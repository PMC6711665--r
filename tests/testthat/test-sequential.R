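test_that("drift correction is exact and antisymmetric at the draw level", {
  # identical lag-n and lag-n+2 draws -> corrected effect exactly zero
  set.seed(5)
  d <- rnorm(400)
  fake <- structure(list(
    mu = cbind(a_low_n = d, a_low_n2 = d,
               v_low_n = d + 1, v_low_n2 = rnorm(400))
  ), class = "ddm_fit")
  eff <- drift_corrected_effect(fake)
  expect_equal(eff$draws$a_low$corrected, rep(0, 400))

  # swapping the lag roles negates every corrected draw
  fit <- fixture_fit()
  e1 <- drift_corrected_effect(fit)
  e2 <- drift_corrected_effect(fit, swap_lags = TRUE)
  for (s in names(e1$draws)) {
    expect_equal(e1$draws[[s]]$corrected, -e2$draws[[s]]$corrected)
  }

  nofit <- structure(list(mu = cbind(a0 = d)), class = "ddm_fit")
  expect_error(drift_corrected_effect(nofit), "no matching")
})

test_that("recovery cohort orders the corrected bound effects correctly", {
  fit <- fixture_fit() # generated with deltas low = .08, pe = .26
  eff <- drift_corrected_effect(fit)
  co <- dplyr::filter(eff$contrasts, parameter == "bound",
                      component == "corrected")
  expect_gt(co$mean, 0)
  expect_gt(co$p_greater, 0.75) # modest cohort; the full-size check is sharper
  pe <- dplyr::filter(eff$summary, parameter == "bound", category == "pe",
                      component == "corrected")
  expect_gt(pe$mean, 0)
})

test_that("matched-trial subsets follow the selection rule exactly", {
  # categories: H L L H L PE (trials 1-6)
  toy <- toy_trials(c(6, 3, 3, 6, 3, 1))
  ms <- matched_trial_subset(toy, "low_vs_high")
  expect_equal(ms$trial[ms$role == "target"], c(2L, 3L, 5L))
  expect_equal(ms$trial[ms$role == "control"], 1L)
  counts <- attr(ms, "counts")
  expect_equal(counts$target, 3L)
  expect_equal(counts$control, 1L)

  # all-high sequence: no targets
  expect_error(matched_trial_subset(toy_trials(rep(6, 6)), "low_vs_high"),
               "target")
  # targets exist but no high trial is followed by one at n+2
  expect_error(matched_trial_subset(toy_trials(c(3, 3, 6, 6)), "low_vs_high"),
               "control")

  # depends only on the category sequence, not block labels
  toy_b <- dplyr::mutate(toy, block = c(1, 1, 2, 2, 3, 3))
  ms_b <- matched_trial_subset(toy_b, "low_vs_high")
  expect_equal(ms$trial, ms_b$trial)
  expect_equal(ms$role, ms_b$role)
})

test_that("stratified fits isolate confidence from objective accuracy", {
  # bound coupled to confidence: the effect survives within correct trials
  trials <- generate_cohort(cohort_config(n_participants = 10,
                                          n_trials = 330, seed = 501))
  sf <- suppressWarnings(suppressMessages(
    stratified_fit(trials, "correct",
                   mcmc = mcmc_control(n_chains = 2, n_samples = 700),
                   seed = 3)))
  pe <- dplyr::filter(tidy(sf), parameter == "bound", category == "pe",
                      component == "corrected")
  expect_gt(pe$mean, 0)

  # bound coupled to previous accuracy only: within the correct stratum the
  # confidence deltas cover zero
  trials_acc <- generate_cohort(cohort_config(
    n_participants = 10, n_trials = 330, seed = 502,
    bound_coupling = "accuracy",
    bound_update = c(high = 0, low = 0, perceived_error = 0.35)))
  sf2 <- suppressWarnings(suppressMessages(
    stratified_fit(trials_acc, "correct",
                   mcmc = mcmc_control(n_chains = 2, n_samples = 700),
                   seed = 4)))
  b <- dplyr::filter(tidy(sf2), parameter == "bound", component == "corrected")
  expect_true(all(b$ci_lo <= 0 & b$ci_hi >= 0))

  # error-only stratum on an all-correct cohort is an error
  allc <- dplyr::mutate(toy_trials(rep(c(6, 3), 20)), coherence = 0.2)
  expect_error(suppressWarnings(stratified_fit(allc, "error")), "no trials")
})
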