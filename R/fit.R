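#' MCMC settings for the hierarchical fit
#'
#' Desk-scale default: 4 chains of 2000 samples, first half burn-in, no
#' thinning. The full-scale setting used for final inference in this line of
#' work is 10 chains of 10000 samples with half burn-in and thinning by 2
#' (`mcmc_control(n_chains = 10, n_samples = 10000, thin = 2)`).
#'
#' @param n_chains Number of independent chains (>= 2 for R-hat).
#' @param n_samples Total MCMC iterations per chain.
#' @param burn_frac Fraction of each chain discarded as burn-in; proposal
#'   adaptation runs only during burn-in.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @return An `mcmc_control` object.
#' @export
mcmc_control <- function(n_chains = 4, n_samples = 2000, burn_frac = 0.5,
                         thin = 1) {
  if (n_chains < 1 || n_samples < 20) abort("mcmc settings too small")
  if (burn_frac <= 0 || burn_frac >= 1) abort("`burn_frac` must be in (0,1)")
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 burn_frac = burn_frac, thin = as.integer(thin)),
            class = "mcmc_control")
}

#' Prior settings for the hierarchical fit
#'
#' Weakly-informative group-level priors: the group-mean baseline bound has a
#' positive-truncated normal prior around 2, non-decision time a
#' positive-truncated normal around 0.3 s, the drift intercept a normal
#' around 1, and all regression coefficients normals centered at 0 with SD 2.
#' Group-level variances have inverse-gamma priors.
#'
#' @param a0 Length-2 `c(mean, sd)` for the group baseline bound.
#' @param ter `c(mean, sd)` for group non-decision time (s).
#' @param v0 `c(mean, sd)` for the group drift intercept.
#' @param coef `c(mean, sd)` for all bound/drift regression coefficients.
#' @param sigma `c(shape, rate)` of the inverse-gamma prior on group
#'   variances.
#' @return A `prior_control` object.
#' @export
prior_control <- function(a0 = c(2, 1), ter = c(0.3, 0.5), v0 = c(1, 2),
                          coef = c(0, 2), sigma = c(2, 0.1)) {
  structure(list(a0 = a0, ter = ter, v0 = v0, coef = coef, sigma = sigma),
            class = "prior_control")
}

#' Fit the hierarchical Bayesian regression diffusion model
#'
#' Estimates group- and participant-level diffusion parameters in which the
#' bound separation and drift rate vary trial-by-trial with the design's
#' regressors (confidence categories at lag n and lag n+2, EEG covariates, or
#' evidence strength). Participant-level parameters are drawn from group-level
#' normal distributions, so sparse cells are shrunk toward the group
#' (statistical inference is meaningful at the group level only). Sampling is
#' Metropolis-within-Gibbs: blocked adaptive random-walk proposals for each
#' participant's bound, drift and non-decision parameters against the exact
#' Wiener first-passage likelihood, and conjugate Gibbs updates for group
#' means and variances. The bound regression uses an identity link; proposals
#' that realize a non-positive bound (or a non-decision time exceeding an
#' observed RT) have likelihood zero and are rejected.
#'
#' @param design A `ddm_design` from [build_design()] or
#'   [eeg_regression_design()].
#' @param mcmc An [mcmc_control()].
#' @param priors A [prior_control()].
#' @param seed Integer seed.
#' @param tol Absolute tolerance of the first-passage density evaluations.
#' @param verbose Print chain progress?
#'
#' @return A `ddm_fit` object holding group-level draws (`mu`, `sigma2`,
#'   one column per parameter), participant-level draws (`theta`), the chain
#'   index of every kept draw, R-hat convergence diagnostics, acceptance and
#'   invalid-proposal rates. Use [tidy()] for summaries,
#'   [drift_corrected_effect()] for sequential effects, [dic()] for model
#'   comparison.
#' @export
fit_ddm_regression <- function(design, mcmc = mcmc_control(),
                               priors = prior_control(), seed = 1,
                               tol = 1e-7, verbose = FALSE) {
  if (!inherits(design, "ddm_design")) abort("`design` must be a ddm_design")
  if (!inherits(mcmc, "mcmc_control")) abort("`mcmc` must be mcmc_control()")
  if (!inherits(priors, "prior_control")) abort("`priors` must be prior_control()")
  dat <- design$data
  ids <- sort(unique(dat$participant))
  J <- length(ids)
  pa <- ncol(design$Xa); pv <- ncol(design$Xv)
  P <- 3L + pa + pv
  par_names <- c("a0", "ter", "v0",
                 if (pa) paste0("a_", colnames(design$Xa)),
                 if (pv) paste0("v_", colnames(design$Xv)))
  ia <- if (pa) 3L + seq_len(pa) else integer(0)
  iv <- if (pv) 3L + pa + seq_len(pv) else integer(0)
  blocks <- list(bound = c(1L, ia), drift = c(3L, iv), ter = 2L)

  pdata <- lapply(ids, function(id) {
    rows <- which(dat$participant == id)
    list(rt = dat$rt[rows], upper = dat$upper[rows],
         Xa = design$Xa[rows, , drop = FALSE],
         Xv = design$Xv[rows, , drop = FALSE])
  })

  loglik_j <- function(pd, th) {
    av <- if (pa) th[1] + drop(pd$Xa %*% th[ia]) else th[1]
    vv <- if (pv) th[3] + drop(pd$Xv %*% th[iv]) else th[3]
    .wfpt_loglik_cpp(pd$rt, pd$upper, av, vv, th[2], 0.5, 1.0, tol)
  }

  # prior hyperparameters by parameter position
  m0 <- c(priors$a0[1], priors$ter[1], priors$v0[1],
          rep(priors$coef[1], pa + pv))
  s0 <- c(priors$a0[2], priors$ter[2], priors$v0[2],
          rep(priors$coef[2], pa + pv))
  truncated <- c(TRUE, TRUE, FALSE, rep(FALSE, pa + pv))
  sig_shape <- priors$sigma[1]; sig_rate <- priors$sigma[2]

  n_samples <- mcmc$n_samples
  burn <- floor(mcmc$burn_frac * n_samples)
  kept_per_chain <- floor((n_samples - burn) / mcmc$thin)
  total_kept <- kept_per_chain * mcmc$n_chains

  mu_draws <- matrix(NA_real_, total_kept, P, dimnames = list(NULL, par_names))
  sig_draws <- matrix(NA_real_, total_kept, P,
                      dimnames = list(NULL, par_names))
  theta_draws <- array(NA_real_, c(total_kept, J, P),
                       dimnames = list(NULL, ids, par_names))
  chain_id <- rep(seq_len(mcmc$n_chains), each = kept_per_chain)

  base_sd <- c(0.12, 0.02, 0.12, rep(0.05, pa + pv))
  ez <- t(vapply(pdata, function(pd) ez_init(pd$rt, pd$upper),
                 numeric(3)))

  set.seed(seed)
  n_prop <- 0; n_invalid <- 0
  acc_tot <- matrix(0, J, 3); acc_n <- 0
  k_out <- 0L
  for (ch in seq_len(mcmc$n_chains)) {
    theta <- matrix(0, J, P, dimnames = list(ids, par_names))
    theta[, 1] <- ez[, 1] * exp(rnorm(J, 0, 0.08))
    theta[, 2] <- pmax(0.03, ez[, 2] + rnorm(J, 0, 0.02))
    theta[, 3] <- ez[, 3] * exp(rnorm(J, 0, 0.08))
    if (pa + pv > 0) theta[, 4:P] <- rnorm(J * (pa + pv), 0, 0.02)
    mu <- colMeans(theta)
    sig2 <- pmax(apply(theta, 2, var), 0.02)
    ll <- vapply(seq_len(J), function(j) loglik_j(pdata[[j]], theta[j, ]),
                 numeric(1))
    if (any(!is.finite(ll))) {
      # nudge invalid starts to a safe configuration
      for (j in which(!is.finite(ll))) {
        theta[j, ] <- c(2, max(0.02, min(pdata[[j]]$rt) / 2), 1,
                        rep(0, pa + pv))
        ll[j] <- loglik_j(pdata[[j]], theta[j, ])
      }
    }
    lambda <- matrix(0.6, J, 3)
    acc_win <- matrix(0, J, 3)
    s_sum <- matrix(0, J, P); s_sq <- matrix(0, J, P); s_n <- 0
    prop_sd <- matrix(base_sd, J, P, byrow = TRUE)

    for (it in seq_len(n_samples)) {
      for (j in seq_len(J)) {
        th <- theta[j, ]
        for (b in 1:3) {
          idx <- blocks[[b]]
          prop <- th
          prop[idx] <- th[idx] + lambda[j, b] * prop_sd[j, idx] *
            rnorm(length(idx))
          n_prop <- n_prop + 1
          llp <- loglik_j(pdata[[j]], prop)
          if (!is.finite(llp)) {
            n_invalid <- n_invalid + 1
            next
          }
          lr <- llp - ll[j] +
            sum(dnorm(prop[idx], mu[idx], sqrt(sig2[idx]), log = TRUE)) -
            sum(dnorm(th[idx], mu[idx], sqrt(sig2[idx]), log = TRUE))
          if (log(runif(1)) < lr) {
            th <- prop; ll[j] <- llp
            acc_win[j, b] <- acc_win[j, b] + 1
            if (it > burn) acc_tot[j, b] <- acc_tot[j, b] + 1
          }
        }
        theta[j, ] <- th
      }
      if (it > burn) acc_n <- acc_n + 1

      # conjugate group-level updates
      for (p in seq_len(P)) {
        xb <- theta[, p]
        prec <- J / sig2[p] + 1 / s0[p]^2
        mpost <- (sum(xb) / sig2[p] + m0[p] / s0[p]^2) / prec
        sdpost <- sqrt(1 / prec)
        mu[p] <- if (truncated[p]) {
          rtrunc_norm_pos(mpost, sdpost)
        } else {
          rnorm(1, mpost, sdpost)
        }
        sig2[p] <- 1 / stats::rgamma(1, shape = sig_shape + J / 2,
                                     rate = sig_rate +
                                       0.5 * sum((xb - mu[p])^2))
      }

      # adaptation during burn-in only
      if (it <= burn) {
        s_sum <- s_sum + theta; s_sq <- s_sq + theta^2; s_n <- s_n + 1
        if (it %% 50 == 0) {
          rate <- acc_win / 50
          lambda <- lambda * exp(0.4 * (rate - 0.25))
          lambda[lambda > 10] <- 10
          lambda[lambda < 1e-3] <- 1e-3
          acc_win[] <- 0
          if (s_n >= 200) {
            v <- pmax(s_sq / s_n - (s_sum / s_n)^2, 0)
            prop_sd <- pmax(sqrt(v), matrix(base_sd / 20, J, P, byrow = TRUE))
          }
        }
      } else if ((it - burn) %% mcmc$thin == 0) {
        k_out <- k_out + 1L
        mu_draws[k_out, ] <- mu
        sig_draws[k_out, ] <- sig2
        theta_draws[k_out, , ] <- theta
      }
    }
    if (verbose) {
      inform(sprintf("chain %d/%d done (mean accept %.2f)",
                     ch, mcmc$n_chains, mean(acc_tot / max(acc_n, 1))))
    }
  }

  rh <- vapply(seq_len(P), function(p) {
    rhat(matrix(mu_draws[, p], ncol = mcmc$n_chains))
  }, numeric(1))
  names(rh) <- par_names
  invalid_rate <- n_invalid / max(n_prop, 1)
  if (invalid_rate > 0.01) {
    warn(sprintf("%.1f%% of proposals had invalid likelihood (rejected)",
                 100 * invalid_rate))
  }
  if (any(rh < 0.98 | rh > 1.02)) {
    warn(paste("convergence warning: R-hat outside [0.98, 1.02] for",
               paste(par_names[rh < 0.98 | rh > 1.02], collapse = ", ")))
  }

  structure(
    list(mu = mu_draws, sigma2 = sig_draws, theta = theta_draws,
         chain = chain_id, par_names = par_names, participants = ids,
         rhat = rh, accept = acc_tot / max(acc_n, 1),
         invalid_rate = invalid_rate,
         mcmc = mcmc, priors = priors, seed = seed,
         design_info = list(Xa = colnames(design$Xa),
                            Xv = colnames(design$Xv),
                            n_trials = nrow(dat),
                            dropped = design$dropped)),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "<ddm_fit> %d group parameters, %d participants, %d kept draws (%d chains)\n",
    length(x$par_names), length(x$participants), nrow(x$mu),
    x$mcmc$n_chains
  ))
  cat(sprintf("R-hat range: [%.3f, %.3f]; invalid-proposal rate %.2g\n",
              min(x$rhat), max(x$rhat), x$invalid_rate))
  print(tidy(x))
  invisible(x)
}

#' Posterior draws of a group-level parameter
#'
#' @param fit A `ddm_fit`.
#' @param parameter Parameter name (see `fit$par_names`).
#' @return Numeric vector of kept group-mean draws.
#' @export
posterior_draws <- function(fit, parameter) {
  if (!inherits(fit, "ddm_fit")) abort("`fit` must be a ddm_fit")
  if (!parameter %in% colnames(fit$mu)) {
    abort(sprintf("unknown parameter `%s`", parameter))
  }
  fit$mu[, parameter]
}

#' @export
tidy.ddm_fit <- function(x, level = c("group", "participant"),
                         conf_level = 0.95, ...) {
  level <- match.arg(level)
  al <- (1 - conf_level) / 2
  if (level == "group") {
    purrr::map_dfr(x$par_names, function(p) {
      d <- x$mu[, p]
      tibble(
        parameter = p,
        mean = mean(d), sd = sd(d),
        ci_lo = unname(quantile(d, al)), ci_hi = unname(quantile(d, 1 - al)),
        rhat = unname(x$rhat[p]),
        p_zero = if (p %in% c("a0", "ter", "v0")) NA_real_ else posterior_p(d)
      )
    })
  } else {
    # participant-level summaries are shrunken by the group prior and are
    # not valid for between-participant inference
    grid <- expand.grid(participant = x$participants,
                        parameter = x$par_names, stringsAsFactors = FALSE)
    purrr::map2_dfr(grid$participant, grid$parameter, function(id, p) {
      d <- x$theta[, as.character(id), p]
      tibble(participant = id, parameter = p, mean = mean(d), sd = sd(d))
    })
  }
}

#' @export
glance.ddm_fit <- function(x, ...) {
  tibble(
    n_parameters = length(x$par_names),
    n_participants = length(x$participants),
    n_trials = x$design_info$n_trials,
    n_chains = x$mcmc$n_chains,
    n_kept = nrow(x$mu),
    max_rhat = max(x$rhat),
    min_rhat = min(x$rhat),
    invalid_rate = x$invalid_rate
  )
}

# --- internal ---------------------------------------------------------------

# positive-truncated normal draw by inverse-cdf
rtrunc_norm_pos <- function(m, s) {
  lo <- pnorm(0, m, s)
  u <- runif(1, lo, 1)
  u <- min(u, 1 - 1e-16)
  qnorm(u, m, s)
}

# EZ-style moment initialization (unit noise)
ez_init <- function(rt, upper) {
  n <- length(rt)
  p <- mean(upper)
  p <- min(max(p, 0.5 + 1 / (2 * n)), 1 - 1 / (2 * n))
  L <- qlogis(p)
  vrt <- max(var(rt), 1e-4)
  x <- L * (L * p^2 - L * p + p - 0.5) / vrt
  v <- max(0.1, min(3, abs(x)^0.25))
  a <- max(0.6, min(4, L / v))
  mdt <- (a / (2 * v)) * tanh(a * v / 2)
  ter <- max(0.03, min(mean(rt) - mdt, min(rt) - 0.03))
  c(a0 = a, ter = ter, v0 = v)
}
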