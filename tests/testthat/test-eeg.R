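test_that("window means respect the filter and the window", {
  times <- seq(-200, 600, by = 2) # 500 Hz sampling
  # constant epoch passes through the filter unchanged
  expect_equal(window_mean(rep(3.3, length(times)), times,
                           epoch_window("ERN")), 3.3, tolerance = 1e-3)
  # a 40 Hz oscillation is suppressed by the 10 Hz low-pass
  x40 <- 5 * sin(2 * pi * 40 * times / 1000)
  expect_lt(abs(window_mean(x40, times, epoch_window("Pe"))), 0.05)
  # plain arithmetic mean without filtering
  expect_equal(window_mean(c(1, 2, 3, 4, 5), 0:4 * 10, window = c(0, 40),
                           lowpass = NA), 3.0)
  # window outside the epoch is an error
  expect_error(window_mean(1:5, 0:4 * 10, window = c(0, 100), lowpass = NA),
               "outside")
  # component defaults
  expect_equal(epoch_window("ERN")$window, c(-10, 90))
  expect_equal(epoch_window("ERN")$electrode, "FCz")
  expect_equal(epoch_window("Pe")$window, c(250, 350))
  expect_equal(epoch_window("Pe")$electrode, "Pz")
})

test_that("long-format epochs reduce to merged single-trial amplitudes", {
  times <- seq(0, 500, by = 4)
  epochs <- tidyr::expand_grid(participant = 1, trial = 1:3,
                               electrode = c("Pz", "FCz"),
                               time_ms = times) |>
    dplyr::mutate(amplitude = trial * 1.0)
  amps <- extract_amplitudes(epochs, epoch_window("Pe"))
  expect_equal(nrow(amps), 3)
  expect_equal(amps$amplitude, c(1, 2, 3), tolerance = 1e-3)
  expect_error(extract_amplitudes(epochs, epoch_window("Pe", electrode = "Oz")),
               "not present")
})

test_that("rank transform uses average ranks and is monotone invariant", {
  expect_equal(rank_transform(c(1.2, -0.5, 3.3)), c(2, 1, 3))
  expect_equal(rank_transform(c(1, 1, 2)), c(1.5, 1.5, 3))
  x <- rnorm(50)
  expect_equal(rank_transform(x), rank_transform(exp(x)))
  expect_error(rank_transform(1), "at least 2")
})

test_that("ERN residualization is exact least squares", {
  expect_equal(residualize_pe(c(1, 3, 5), c(0, 1, 2)), rep(0, 3),
               tolerance = 1e-10)
  set.seed(8)
  pe <- rnorm(40)
  ern <- rnorm(40)
  res <- residualize_pe(pe, ern)
  expect_equal(sum(res), 0, tolerance = 1e-10)
  expect_equal(sum(res * ern), 0, tolerance = 1e-10)
  expect_warning(r0 <- residualize_pe(pe, rep(1, 40)), "zero-variance")
  expect_equal(r0, pe - mean(pe))
})

test_that("quantile bins are equal-count with remainder to lower bins", {
  expect_equal(as.vector(table(pe_quantile_bins(rnorm(10)))), rep(2, 5))
  expect_equal(as.vector(table(pe_quantile_bins(rnorm(12)))),
               c(3, 3, 2, 2, 2))
  x <- rnorm(37)
  expect_equal(pe_quantile_bins(x), pe_quantile_bins(2 * x + 5))
  expect_equal(pe_quantile_bins(x), pe_quantile_bins(qnorm(pnorm(x))))
  # labels ascend with amplitude
  b <- pe_quantile_bins(x)
  expect_true(all(diff(tapply(x, b, mean)) > 0))
  expect_error(pe_quantile_bins(rnorm(3), k = 5), "at least 5")
})

test_that("EEG designs code reference bins and raw-vs-residual binning agrees
           exactly when Pe and ERN are uncorrelated", {
  trials <- generate_cohort(cohort_config(n_participants = 4, n_trials = 120,
                                          seed = 601))
  db <- suppressMessages(eeg_regression_design(trials, mode = "binned"))
  # trial in bin 1 at both lags -> all indicators zero
  ref <- rowSums(db$Xa) == 0
  expect_gt(sum(ref), 0)
  dc <- suppressMessages(eeg_regression_design(trials, mode = "continuous"))
  expect_equal(colnames(dc$Xa),
               c("pe_rank_n", "ern_rank_n", "pe_rank_n2", "ern_rank_n2"))

  # force exactly zero in-sample Pe-ERN correlation per participant: the
  # residualization is then the identity up to centering, so bins agree
  tr0 <- trials |>
    dplyr::group_by(participant) |>
    dplyr::mutate(ern_amp = residualize_pe(ern_amp, pe_amp)) |>
    dplyr::ungroup()
  braw <- suppressMessages(eeg_regression_design(tr0, mode = "binned",
                                                 residualize = FALSE))
  bres <- suppressMessages(eeg_regression_design(tr0, mode = "binned",
                                                 residualize = TRUE))
  expect_equal(braw$Xa, bres$Xa)

  # missing EEG beyond 10% raises a hard warning
  tr_na <- trials
  tr_na$pe_amp[seq_len(round(nrow(tr_na) * 0.2))] <- NA
  expect_warning(suppressMessages(eeg_regression_design(tr_na)), "10%")
})
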