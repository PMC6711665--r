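#' Gelman-Rubin potential scale reduction (R-hat)
#'
#' Classic R-hat comparing within-chain and between-chain variance of the
#' post-burn-in draws. The statistic depends on chains only through their
#' means and variances, so permuting iterations within a chain leaves it
#' unchanged. Values near 1 (conventionally within \[0.98, 1.02\]) indicate
#' convergence.
#'
#' @param draws Matrix of draws with one column per chain (equal lengths), or
#'   a list of equal-length numeric vectors.
#' @return The scalar R-hat.
#' @examples
#' rhat(cbind(rnorm(500), rnorm(500)))
#' @export
rhat <- function(draws) {
  if (is.list(draws) && !is.data.frame(draws)) {
    if (length(unique(lengths(draws))) != 1) {
      abort("all chains must have the same length")
    }
    draws <- do.call(cbind, draws)
  }
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) abort("R-hat requires at least 2 chains")
  if (n < 2) abort("chains must contain at least 2 draws")
  means <- colMeans(draws)
  W <- mean(apply(draws, 2, var))
  B <- n * var(means)
  if (W <= 0) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Posterior-overlap p-value
#'
#' Two-sided probability that a posterior difference distribution overlaps
#' zero: `p = 2 * min(Pr(d > 0), Pr(d < 0))`, estimated from the draws. When
#' no draw crosses zero the Monte-Carlo resolution floor `1/N` is reported
#' (attribute `at_floor`), to be read as "p < 1/N". A one-sided version
#' halves the value.
#'
#' @param draws Numeric vector of posterior draws of a difference/effect.
#' @param alternative `"two_sided"` (default) or `"one_sided"`.
#' @return The p-value, with attribute `at_floor`.
#' @examples
#' posterior_p(c(-1, rep(1, 9))) # 0.2
#' @export
posterior_p <- function(draws, alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) abort("need at least 2 draws")
  tail_min <- min(mean(draws > 0), mean(draws < 0))
  p <- if (alternative == "two_sided") 2 * tail_min else tail_min
  at_floor <- tail_min == 0
  p <- max(p, 1 / n)
  p <- min(p, 1)
  attr(p, "at_floor") <- at_floor
  p
}

#' Deviance information criterion
#'
#' `DIC = mean deviance + p_D` with effective parameter count
#' `p_D = mean deviance - deviance at the posterior mean`. Lower is better; a
#' difference of about 10 is conventionally meaningful.
#'
#' @param object Posterior draws: a `ddm_fit` (uses the participant-level
#'   draws and the fitted design's trial data) or a matrix of parameter draws
#'   (one row per draw) with a log-likelihood function.
#' @param ... Passed to methods.
#' @return A tibble with `dic`, `mean_deviance` and `p_d`.
#' @export
dic <- function(object, ...) UseMethod("dic")

#' @rdname dic
#' @param loglik Function mapping one parameter vector (a row of the draw
#'   matrix) to the model's total log-likelihood.
#' @export
dic.matrix <- function(object, loglik, ...) {
  dev <- apply(object, 1, function(par) -2 * loglik(par))
  dev_hat <- -2 * loglik(colMeans(object))
  tibble(dic = mean(dev) + (mean(dev) - dev_hat),
         mean_deviance = mean(dev),
         p_d = mean(dev) - dev_hat)
}

#' @rdname dic
#' @param design The `ddm_design` the fit was estimated from.
#' @param n_draws Number of posterior draws used for the deviance average
#'   (subsampled deterministically; the deviance at the posterior mean uses
#'   all draws).
#' @param tol Absolute tolerance of the first-passage density evaluations.
#' @export
dic.ddm_fit <- function(object, design, n_draws = 200, tol = 1e-7, ...) {
  if (!inherits(design, "ddm_design")) abort("`design` must be a ddm_design")
  dat <- design$data
  ids <- object$participants
  pa <- length(object$design_info$Xa); pv <- length(object$design_info$Xv)
  ia <- if (pa) 3L + seq_len(pa) else integer(0)
  iv <- if (pv) 3L + pa + seq_len(pv) else integer(0)
  pdata <- lapply(ids, function(id) {
    rows <- which(dat$participant == id)
    list(rt = dat$rt[rows], upper = dat$upper[rows],
         Xa = design$Xa[rows, , drop = FALSE],
         Xv = design$Xv[rows, , drop = FALSE])
  })
  ll_all <- function(th_mat) { # th_mat: J x P participant parameters
    sum(vapply(seq_along(ids), function(j) {
      th <- th_mat[j, ]
      av <- if (pa) th[1] + drop(pdata[[j]]$Xa %*% th[ia]) else th[1]
      vv <- if (pv) th[3] + drop(pdata[[j]]$Xv %*% th[iv]) else th[3]
      .wfpt_loglik_cpp(pdata[[j]]$rt, pdata[[j]]$upper, av, vv, th[2],
                       0.5, 1.0, tol)
    }, numeric(1)))
  }
  K <- dim(object$theta)[1]
  take <- unique(round(seq(1, K, length.out = min(n_draws, K))))
  dev <- vapply(take, function(k) -2 * ll_all(object$theta[k, , ]),
                numeric(1))
  theta_bar <- apply(object$theta, c(2, 3), mean)
  dev_hat <- -2 * ll_all(theta_bar)
  dbar <- mean(dev)
  tibble(dic = dbar + (dbar - dev_hat), mean_deviance = dbar,
         p_d = dbar - dev_hat)
}
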