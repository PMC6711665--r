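test_that("confidence binning is the fixed three-level partition", {
  expect_equal(as.character(bin_confidence(c(6, 5))), c("high", "high"))
  expect_equal(as.character(bin_confidence(c(4, 3))), c("low", "low"))
  expect_equal(as.character(bin_confidence(c(2, 1))),
               c("perceived_error", "perceived_error"))
  expect_error(bin_confidence(0), "1..6")
  expect_error(bin_confidence(7), "1..6")
  expect_error(bin_confidence(NA), "1..6")
  # total on the generator's output: no missing categories
  trials <- fixture_cohort()
  expect_false(anyNA(bin_confidence(trials$confidence_rating)))
})

test_that("caution statistic reproduces hand-computed cells", {
  # previous-category high trials with RTs .6/.8/1 and accuracies 1/1/0
  toy <- toy_trials(ratings = c(6, 6, 5, 6), rt = c(0.5, 0.6, 0.8, 1.0),
                    accuracy = c(1L, 1L, 1L, 0L))
  cs <- caution_statistic(toy)
  cell <- dplyr::filter(cs$by_participant, reference == "trial_n",
                        category == "high")
  expect_equal(cell$rt_central, 0.8)
  expect_equal(cell$accuracy, 2 / 3)
  expect_equal(cell$caution, 0.8 * 2 / 3, tolerance = 1e-6)

  # all accuracies 1: caution equals the central RT; no perceived-error
  # predecessors, so that cell stays missing
  toy2 <- toy_trials(ratings = c(6, 3, 3, 6, 5), rt = c(1, 2, 3, 4, 5))
  cs2 <- caution_statistic(toy2, rt_center = "mean")
  bp <- dplyr::filter(cs2$by_participant, reference == "trial_n", n > 0)
  expect_equal(bp$caution, bp$rt_central)

  # empty cells stay missing, never imputed
  expect_true(any(is.na(dplyr::filter(cs2$by_participant,
                                      reference == "trial_n")$caution)))
})

test_that("caution lag alignment is consistent under time reversal", {
  trials <- dplyr::filter(fixture_cohort(), participant <= 3)
  rev_trials <- trials |>
    dplyr::group_by(participant) |>
    dplyr::mutate(trial = rev(trial)) |>
    dplyr::ungroup()
  a <- caution_statistic(trials, lag = -1)$by_participant
  b <- caution_statistic(rev_trials, lag = 1)$by_participant
  cols <- c("participant", "category", "n", "rt_central", "accuracy")
  expect_equal(
    dplyr::arrange(dplyr::filter(a, reference == "trial_n")[cols],
                   participant, category),
    dplyr::arrange(dplyr::filter(b, reference == "trial_n")[cols],
                   participant, category)
  )
})

test_that("caution after perceived errors exceeds caution after high confidence", {
  cs <- caution_statistic(fixture_cohort())
  g <- cs$group[cs$group$reference == "trial_n", ]
  expect_gt(g$caution[g$category == "perceived_error"],
            g$caution[g$category == "high"])
  # and the corrected delta keeps the direction
  d <- dplyr::filter(cs$deltas, category == "perceived_error",
                     component == "corrected")
  expect_gt(d$mean, 0)
})

test_that("accuracy-by-confidence handles missing and degenerate levels", {
  toy <- toy_trials(ratings = c(6, 6, 1, 1), accuracy = c(1L, 1L, 0L, 1L))
  res <- accuracy_by_confidence(toy)
  expect_equal(nrow(res), 6)
  expect_true(is.na(res$accuracy[res$rating == 3]))
  # all-correct input reports 1.0 everywhere observed
  allc <- toy_trials(ratings = c(6, 5, 4, 3), accuracy = rep(1L, 4))
  resc <- accuracy_by_confidence(allc)
  expect_true(all(resc$accuracy[!is.na(resc$accuracy)] == 1))
  # calibrated cohort: accuracy monotone nondecreasing in rating
  resg <- accuracy_by_confidence(fixture_cohort())
  expect_true(all(diff(resg$acc_pooled) >= 0))
})

test_that("spectral slope estimator is calibrated and scale invariant", {
  slopes <- vapply(1:200, function(s) {
    set.seed(s)
    as.numeric(spectral_slope(rnorm(4096)))
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.05)

  set.seed(2)
  x <- rnorm(512)
  expect_equal(as.numeric(spectral_slope(x)),
               as.numeric(spectral_slope(17.3 * x)), tolerance = 1e-10)

  expect_error(spectral_slope(rep(1, 128)), "constant")
  expect_error(spectral_slope(rnorm(32)), "64")
  expect_error(spectral_slope(c(rnorm(100), NA)), "missing")
  expect_message(
    s <- spectral_slope(c(rnorm(200), NA), na_action = "interpolate"),
    "interpolate"
  )
  expect_true(is.finite(s))
})
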