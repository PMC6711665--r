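test_that("cohort generation is reproducible and validates its config", {
  cfg <- cohort_config(n_participants = 2, n_trials = 60, seed = 4)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1, t2)
  expect_setequal(unique(t1$participant), 1:2)
  expect_true(all(t1$rt > 0))
  # accuracy is consistent with stimulus and choice
  expect_identical(t1$accuracy, as.integer(t1$stimulus == t1$choice))
  # category consistent with rating via the binning rule
  expect_identical(t1$confidence_category, bin_confidence(t1$confidence_rating))

  expect_error(cohort_config(confidence_thresholds = c(1, 2, 3, 4)), "5")
  expect_error(cohort_config(coherence_levels = c(-0.1, 0.2)), ">= 0")
  # a bound update that drives a_t below zero is a hard error
  bad <- cohort_config(n_participants = 1, n_trials = 80, seed = 1,
                       bound_update = c(high = 0, low = -5,
                                        perceived_error = 0))
  expect_error(generate_cohort(bad), "non-positive bound")
})

test_that("default calibration reproduces the observed confidence-category mix", {
  trials <- fixture_cohort() # 8 participants x 330 trials, defaults
  counts <- table(trials$confidence_category) / length(unique(trials$participant))
  # reported per-participant means: 191.7 high, 114.5 low, 23.8 perceived
  # error (of ~330 rated trials); generator must land within +-50%
  expect_gt(counts[["high"]], 191.7 * 0.5)
  expect_lt(counts[["high"]], 191.7 * 1.5)
  expect_gt(counts[["low"]], 114.5 * 0.5)
  expect_lt(counts[["low"]], 114.5 * 1.5)
  expect_gt(counts[["perceived_error"]], 23.8 * 0.5)
  expect_lt(counts[["perceived_error"]], 23.8 * 1.5)
})

test_that("accuracy rises with coherence and confidence tracks accuracy", {
  trials <- fixture_cohort()
  acc <- tapply(trials$accuracy, trials$coherence, mean)
  expect_true(all(diff(acc) > 0))
  # perceived errors really are mostly errors (below-chance accuracy)
  expect_lt(mean(trials$accuracy[trials$confidence_rating <= 2]), 0.5)
  # higher-rated trials are more accurate overall
  accr <- tapply(trials$accuracy, trials$confidence_rating, mean)
  expect_true(all(diff(accr) >= 0))
})

test_that("post-decisional evidence maps onto ratings as specified", {
  th <- c(-1, -0.5, 0, 0.5, 1)
  expect_equal(postdecision_confidence(10, 1, th), 6L)
  expect_true(postdecision_confidence(-10, 1, th) %in% 1:2)
  expect_equal(postdecision_confidence(c(-0.8, 0.2), bound_offset = 0, th),
               c(2L, 4L))
  expect_error(postdecision_confidence(1, 1, c(1, 2)), "5")
})

test_that("EEG-like amplitudes carry the calibrated confidence structure", {
  trials <- fixture_cohort()
  # Pe tracks uncertainty (negated rating)
  expect_gt(cor(trials$pe_amp, -trials$confidence_rating), 0.3)
  # ERN and Pe share variance at roughly the calibrated r = 0.18
  r <- cor(trials$pe_amp, trials$ern_amp)
  expect_gt(r, 0.10)
  expect_lt(r, 0.27)
})

test_that("slow drift gain series has the requested spectral structure", {
  expect_identical(apply_slow_drift(128, -1, 0), rep(1, 128))
  g <- apply_slow_drift(4096, -1, 0.3, seed = 1)
  expect_true(all(g > 0))
  expect_equal(mean(g), 1, tolerance = 1e-2)
  # generator/estimator round trip at beta = -0.5
  slopes <- vapply(1:100, function(s) {
    as.numeric(spectral_slope(apply_slow_drift(1024, -0.5, 0.3, seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.5), 0.15)
  expect_error(apply_slow_drift(128, 0.5, 1), "<= 0")
})
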