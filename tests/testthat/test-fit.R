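test_that("R-hat distinguishes mixed from unmixed chains", {
  set.seed(1)
  same <- cbind(rnorm(2000), rnorm(2000), rnorm(2000))
  r <- rhat(same)
  expect_gt(r, 0.98)
  expect_lt(r, 1.02)

  split <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(rhat(split), 1.5)

  # rank-free: permuting iterations within a chain changes nothing
  perm <- apply(same, 2, sample)
  expect_equal(rhat(same), rhat(perm), tolerance = 1e-12)

  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  # list-of-chains input is equivalent to the matrix form
  ch <- list(rnorm(300), rnorm(300, 0.2))
  expect_equal(rhat(ch), rhat(cbind(ch[[1]], ch[[2]])))
})

test_that("posterior-overlap p-values count tail mass", {
  expect_equal(as.numeric(posterior_p(c(-1, rep(1, 9)))), 0.2)
  # symmetric draws give p near 1
  expect_equal(as.numeric(posterior_p(c(-(1:500), 1:500))), 1)
  # all draws positive: floor 1/N, flagged
  p <- posterior_p(rep(1, 2000) + runif(2000))
  expect_equal(as.numeric(p), 1 / 2000)
  expect_true(attr(p, "at_floor"))
  # one-sided halves the two-sided value
  expect_equal(as.numeric(posterior_p(c(-1, rep(1, 9)), "one_sided")), 0.1)
})

test_that("DIC matches hand computation and degenerates correctly", {
  set.seed(3)
  y <- c(0.4, 1.2, 0.9, 1.5)
  # normal-mean model, known-sigma: posterior draws supplied directly
  draws <- matrix(rnorm(4000, mean(y), 0.5), ncol = 1)
  ll <- function(par) sum(dnorm(y, par[1], 1, log = TRUE))
  out <- dic(draws, ll)
  dev <- apply(draws, 1, function(p) -2 * ll(p))
  expect_equal(out$mean_deviance, mean(dev))
  expect_equal(out$p_d, mean(dev) - (-2 * ll(colMeans(draws))))
  expect_equal(out$dic, 2 * mean(dev) + 2 * ll(colMeans(draws)))
  # degenerate posterior: all draws identical -> p_D = 0, DIC = deviance
  dd <- matrix(rep(1, 500), ncol = 1)
  out0 <- dic(dd, ll)
  expect_equal(out0$p_d, 0)
  expect_equal(out0$dic, -2 * ll(1))
})

test_that("log-likelihood is maximized near the generating parameters", {
  p <- ddm_params(a = 2, v = 1, t_er = 0.3)
  wins <- vapply(1:20, function(s) {
    sim <- simulate_ddm(2000, p, dt = 1e-3, seed = 1000 + s)
    ll <- function(a, v) {
      .wfpt_loglik_cpp(sim$rt, sim$choice == "correct", a, v, p$t_er,
                       0.5, 1, 1e-7)
    }
    ll0 <- ll(2, 1)
    all(ll0 > c(ll(2.4, 1), ll(1.6, 1), ll(2, 1.2), ll(2, 0.8)))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("hierarchical fit recovers a null cohort (deltas cover zero)", {
  trials <- generate_cohort(cohort_config(
    n_participants = 8, n_trials = 250, seed = 401,
    bound_update = c(high = 0, low = 0, perceived_error = 0),
    bound_update_sd = 0))
  d <- build_design(trials, regression_spec())
  fit <- suppressWarnings(
    fit_ddm_regression(d, mcmc = mcmc_control(n_chains = 2, n_samples = 700),
                       seed = 12))
  td <- tidy(fit)
  deltas <- td[grepl("^(a|v)_(low|pe)", td$parameter), ]
  expect_true(all(deltas$ci_lo <= 0 & deltas$ci_hi >= 0))
  # structural sanity of the fit object
  expect_s3_class(fit, "ddm_fit")
  expect_equal(nrow(fit$mu), 2 * 350)
  expect_lt(fit$invalid_rate, 0.2)
  g <- glance(fit)
  expect_equal(g$n_chains, 2L)
})

test_that("sparse cells are shrunk toward the group (partial pooling)", {
  fit <- fixture_fit()
  trials <- generate_cohort(cohort_config(n_participants = 8, n_trials = 260,
                                          seed = 302))
  # pick the participant with the fewest perceived-error predecessor trials
  npe <- table(trials$participant[trials$confidence_category == "perceived_error"])
  j <- names(which.min(npe))
  post_mean <- mean(fit$theta[, j, "a_pe_n"])
  group_mean <- mean(fit$mu[, "a_pe_n"])

  # no-pooling reference: per-participant maximum likelihood
  d <- build_design(trials, regression_spec())
  rows <- d$data$participant == as.numeric(j)
  rt <- d$data$rt[rows]; up <- d$data$upper[rows]
  Xa <- d$Xa[rows, ]; Xv <- d$Xv[rows, ]
  nll <- function(par) {
    av <- par[1] + drop(Xa %*% par[4:7])
    vv <- par[3] + drop(Xv %*% par[8:12])
    -.wfpt_loglik_cpp(rt, up, av, vv, par[2], 0.5, 1, 1e-7)
  }
  start <- c(2, min(rt) / 2, 0.5, rep(0, 9))
  ml <- stats::optim(start, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000))
  ml_pe <- ml$par[5]
  expect_lt(abs(post_mean - group_mean), abs(ml_pe - group_mean))
})

test_that("posterior summaries are stable when the MCMC scale is reduced", {
  trials <- generate_cohort(cohort_config(n_participants = 6, n_trials = 220,
                                          seed = 404))
  d <- build_design(trials, regression_spec())
  big <- suppressWarnings(
    fit_ddm_regression(d, mcmc = mcmc_control(n_chains = 3, n_samples = 1200),
                       seed = 1))
  small <- suppressWarnings(
    fit_ddm_regression(d, mcmc = mcmc_control(n_chains = 2, n_samples = 500),
                       seed = 2))
  tb <- tidy(big); ts <- tidy(small)
  m <- merge(tb, ts, by = "parameter", suffixes = c("_big", "_small"))
  m <- m[grepl("^(a|v)_(low|pe)", m$parameter), ]
  expect_true(all(abs(m$mean_big - m$mean_small) < m$sd_big))
})
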