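test_that("first-passage density handles edge cases and symmetry", {
  p <- ddm_params(a = 2, v = 1, t_er = 0.3)
  expect_equal(wfpt_density(c(-1, 0), p), c(0, 0))
  expect_true(all(wfpt_density(seq(0.05, 5, by = 0.05), p) >= 0))

  # zero drift, unbiased start: both bounds are statistically identical
  p0 <- ddm_params(a = 2, v = 0)
  ts <- c(0.1, 0.3, 0.7, 1.5, 3)
  expect_equal(wfpt_density(ts, p0, "upper"), wfpt_density(ts, p0, "lower"))

  expect_error(wfpt_density(c(1, NA), p), "finite")
  expect_error(wfpt_density(1, p, tol = -1), "positive")
  expect_error(ddm_params(a = -1, v = 0), "must be > 0")
  expect_error(ddm_params(a = 1, v = Inf), "finite")
})

test_that("density normalizes and splits mass according to choice probability", {
  for (pars in list(ddm_params(1.5, 0.8), ddm_params(2, 0), ddm_params(3, 2))) {
    up <- wfpt_cdf(80, pars, "upper")
    lo <- wfpt_cdf(80, pars, "lower")
    expect_equal(up + lo, 1, tolerance = 1e-6)
    expect_equal(up, choice_probability(pars), tolerance = 1e-6)
  }
})

test_that("choice probability matches the logistic closed form", {
  expect_equal(choice_probability(ddm_params(2, 0)), 0.5)
  expect_equal(choice_probability(ddm_params(2, 1)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(choice_probability(ddm_params(2, 1)), 0.8808, tolerance = 1e-4)
  # strictly increasing in a * v
  expect_gt(choice_probability(ddm_params(4, 1)),
            choice_probability(ddm_params(2, 1)))
  expect_gt(choice_probability(ddm_params(2, 2)),
            choice_probability(ddm_params(2, 1)))
})

test_that("mean decision time matches the closed form and its v -> 0 limit", {
  expect_equal(mean_decision_time(ddm_params(2, 1)), tanh(1), tolerance = 1e-12)
  expect_equal(mean_decision_time(ddm_params(2, 1)), 0.7616, tolerance = 1e-4)
  expect_equal(mean_decision_time(ddm_params(2, 1e-12)), 1.0, tolerance = 1e-6)
  # continuity at v = 0 and a^2/4 scaling
  expect_equal(mean_decision_time(ddm_params(2, 1e-5)),
               mean_decision_time(ddm_params(2, 0)), tolerance = 1e-6)
  expect_equal(mean_decision_time(ddm_params(4, 0)),
               4 * mean_decision_time(ddm_params(2, 0)))
  expect_error(mean_decision_time(ddm_params(2, 1, w = 0.3)), "w = 0.5")
})

test_that("simulator respects definitions and matches closed-form moments", {
  p <- ddm_params(a = 2, v = 1, t_er = 0.3)
  s <- simulate_ddm(2e4, p, dt = 1e-3, seed = 101)
  expect_true(all(s$rt > p$t_er))
  expect_false(any(s$censored))
  # reproducible given seed
  s2 <- simulate_ddm(2e4, p, dt = 1e-3, seed = 101)
  expect_identical(s$rt, s2$rt)

  # empirical accuracy and mean RT within 3 SE of closed forms
  acc <- mean(s$choice == "correct")
  se_acc <- sqrt(acc * (1 - acc) / nrow(s))
  expect_lt(abs(acc - choice_probability(p)), 3 * se_acc)
  m <- mean(s$rt)
  se_m <- sd(s$rt) / sqrt(nrow(s))
  expect_lt(abs(m - (p$t_er + mean_decision_time(p))), 3 * se_m)

  # driftless process splits 50/50
  s0 <- simulate_ddm(2e4, ddm_params(2, 0), dt = 1e-3, seed = 7)
  acc0 <- mean(s0$choice == "correct")
  expect_lt(abs(acc0 - 0.5), 3 * sqrt(0.25 / 2e4))

  # censoring is flagged, not truncated silently
  sc <- simulate_ddm(200, ddm_params(3, 0), dt = 1e-3, seed = 3,
                     max_time = 0.05)
  expect_true(any(sc$censored))
  expect_true(all(is.na(sc$choice[sc$censored])))
})

test_that("simulated decision times agree with the analytic distribution", {
  p <- ddm_params(a = 2, v = 1)
  s <- simulate_ddm(1e5, p, dt = 1e-3, seed = 5)
  ks_up <- wfpt_ks(s$rt[s$choice == "correct"], p, "upper")
  expect_lt(ks_up, 0.01)
})
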