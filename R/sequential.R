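#' Drift-corrected sequential effects from a joint fit
#'
#' For every bound/drift regressor that appears at both lag n and lag n+2 in
#' the same fit (suffixes `_n` and `_n2`), computes the drawwise difference
#' of group posteriors (lag n minus lag n+2). Because confidence two trials
#' ahead cannot causally affect the intervening trial, its coefficient proxies
#' slow performance drift, and the difference isolates the rapid,
#' confidence-driven adjustment. Posterior-overlap p-values are attached to
#' the raw lag-n, raw lag-n+2 and corrected distributions, and drawwise
#' between-category contrasts (e.g. perceived-error minus low) are emitted
#' for both the corrected and the raw lag-n effects.
#'
#' @param fit A `ddm_fit` whose design contains matching `_n` / `_n2` terms.
#' @param swap_lags Swap the roles of lag n and lag n+2 (the corrected
#'   distributions are exactly negated); mainly a consistency check.
#' @return A `sequential_effect` object: `summary` tibble (parameter x
#'   category x component with mean, sd, 95% interval, p), `contrasts`
#'   tibble, and the underlying draws in `draws`.
#' @export
drift_corrected_effect <- function(fit, swap_lags = FALSE) {
  if (!inherits(fit, "ddm_fit")) abort("`fit` must be a ddm_fit")
  nm <- colnames(fit$mu)
  n_terms <- grep("_n$", nm, value = TRUE)
  stems <- sub("_n$", "", n_terms)
  stems <- stems[paste0(stems, "_n2") %in% nm]
  if (length(stems) == 0) {
    abort("fit contains no matching lag-n / lag-n+2 coefficient pairs")
  }
  draws <- list()
  rows <- list()
  for (s in stems) {
    par <- if (startsWith(s, "a_")) "bound" else if (startsWith(s, "v_"))
      "drift" else "other"
    category <- sub("^[av]_", "", s)
    d_n <- fit$mu[, paste0(s, "_n")]
    d_n2 <- fit$mu[, paste0(s, "_n2")]
    if (swap_lags) { tmp <- d_n; d_n <- d_n2; d_n2 <- tmp }
    corr <- d_n - d_n2
    draws[[s]] <- list(raw_n = d_n, raw_n2 = d_n2, corrected = corr)
    rows[[s]] <- purrr::map2_dfr(
      list(d_n, d_n2, corr), c("raw_n", "raw_n2", "corrected"),
      function(d, comp) {
        tibble(parameter = par, category = category, component = comp,
               mean = mean(d), sd = sd(d),
               ci_lo = unname(quantile(d, 0.025)),
               ci_hi = unname(quantile(d, 0.975)),
               p = as.numeric(posterior_p(d)))
      })
  }
  summary <- dplyr::bind_rows(rows)

  contrasts <- NULL
  cats <- unique(summary$category)
  if (all(c("low", "pe") %in% cats)) {
    contrasts <- purrr::map_dfr(c("bound", "drift"), function(par) {
      pre <- if (par == "bound") "a_" else "v_"
      if (!all(paste0(pre, c("low", "pe"), "_n") %in% nm)) return(NULL)
      purrr::map_dfr(c("corrected", "raw_n"), function(comp) {
        d <- draws[[paste0(pre, "pe")]][[comp]] -
          draws[[paste0(pre, "low")]][[comp]]
        tibble(parameter = par, contrast = "pe_minus_low", component = comp,
               mean = mean(d), sd = sd(d),
               ci_lo = unname(quantile(d, 0.025)),
               ci_hi = unname(quantile(d, 0.975)),
               p = as.numeric(posterior_p(d)),
               p_greater = mean(d > 0))
      })
    })
  }

  structure(list(summary = summary, contrasts = contrasts, draws = draws,
                 swap_lags = swap_lags),
            class = "sequential_effect")
}

#' @export
print.sequential_effect <- function(x, ...) {
  cat("<sequential_effect> lag-n vs lag-n+2 corrected posteriors\n")
  print(x$summary)
  if (!is.null(x$contrasts)) {
    cat("between-category contrasts:\n")
    print(x$contrasts)
  }
  invisible(x)
}

#' @export
tidy.sequential_effect <- function(x, ...) x$summary

#' Matched-trial control subset
#'
#' Selects, per participant, target trials whose confidence falls in the
#' contrast category, and control trials with high confidence whose trial n+2
#' falls in that same category. Both trial types therefore neighbor a
#' low-confidence (or perceived-error) trial and stem from statistically
#' similar slow-drift states; comparing behavior after targets versus after
#' controls re-tests the sequential effect without the lag-n+2 regression
#' subtraction. The selection depends only on the within-participant category
#' sequence (block labels are ignored).
#'
#' @param trials Trial table with `participant`, `trial` and
#'   `confidence_category` (or `confidence_rating`).
#' @param contrast `"low_vs_high"` or `"pe_vs_high"`.
#' @return The anchor trials (rows of `trials`) with a `role` column
#'   (`"target"` / `"control"`); per-participant counts in attribute
#'   `"counts"`.
#' @export
matched_trial_subset <- function(trials,
                                 contrast = c("low_vs_high", "pe_vs_high")) {
  contrast <- match.arg(contrast)
  target <- if (contrast == "low_vs_high") "low" else "perceived_error"
  trials <- ensure_categories(trials)
  out <- trials |>
    arrange(.data$participant, .data$trial) |>
    group_by(.data$participant) |>
    mutate(
      cat2 = dplyr::lead(.data$confidence_category, 2L),
      role = dplyr::case_when(
        .data$confidence_category == target ~ "target",
        .data$confidence_category == "high" & !is.na(.data$cat2) &
          .data$cat2 == target ~ "control",
        TRUE ~ NA_character_
      )
    ) |>
    ungroup() |>
    filter(!is.na(.data$role)) |>
    select(-"cat2")
  if (!any(out$role == "target")) {
    abort(sprintf("no trials in the target category `%s`", target))
  }
  if (!any(out$role == "control")) {
    abort("no high-confidence control trials with the target category at trial n+2")
  }
  counts <- out |>
    dplyr::count(.data$participant, .data$role) |>
    tidyr::pivot_wider(names_from = "role", values_from = "n",
                       values_fill = 0L)
  attr(out, "counts") <- counts
  out
}

#' Accuracy-stratified sequential fit
#'
#' Re-runs the full pipeline (design, hierarchical fit, drift-corrected
#' effects) on the subset of outcome trials whose predictor trial (trial n,
#' the one providing the confidence rating) was correct, or was an error.
#' A surviving confidence effect within a single accuracy stratum shows the
#' bound adjustment tracks the internal confidence signal rather than
#' objective accuracy. Participants lacking trials in any confidence
#' category within the stratum are dropped (and counted), since their cells
#' would be empty.
#'
#' @param trials Trial table.
#' @param stratum `"correct"` or `"error"`: accuracy of the predictor trial.
#' @param spec,mcmc,priors,seed,verbose Passed to [build_design()] and
#'   [fit_ddm_regression()].
#' @param lag_across_blocks Passed to [build_design()].
#' @return A list (class `stratified_fit`) with the `ddm_fit`, the
#'   `sequential_effect`, the stratum, and the dropped participants.
#' @export
stratified_fit <- function(trials, stratum = c("correct", "error"),
                           spec = regression_spec(), mcmc = mcmc_control(),
                           priors = prior_control(), seed = 1,
                           lag_across_blocks = TRUE, verbose = FALSE) {
  stratum <- match.arg(stratum)
  design <- build_design(trials, spec, lag_across_blocks = lag_across_blocks)
  want <- if (stratum == "correct") 1 else 0
  keep <- design$data$prev_accuracy == want
  if (!any(keep)) abort(sprintf("stratum `%s` contains no trials", stratum))
  dat <- design$data[keep, , drop = FALSE]
  Xa <- design$Xa[keep, , drop = FALSE]
  Xv <- design$Xv[keep, , drop = FALSE]

  cells <- dat |>
    dplyr::count(.data$participant, .data$conf_prev, .drop = FALSE) |>
    group_by(.data$participant) |>
    summarise(complete = all(.data$n > 0), .groups = "drop")
  dropped <- cells$participant[!cells$complete]
  if (length(dropped) > 0) {
    inform(sprintf(
      "stratified_fit: dropped %d participant(s) lacking a confidence cell in the %s stratum",
      length(dropped), stratum))
    keep2 <- !dat$participant %in% dropped
    dat <- dat[keep2, , drop = FALSE]
    Xa <- Xa[keep2, , drop = FALSE]
    Xv <- Xv[keep2, , drop = FALSE]
  }
  if (nrow(dat) == 0 || dplyr::n_distinct(dat$participant) < 2) {
    abort(sprintf("stratum `%s` leaves too few participants to fit", stratum))
  }
  sub <- structure(
    list(data = dat, Xa = Xa, Xv = Xv,
         dropped = dplyr::bind_rows(
           design$dropped,
           tibble(reason = "outside stratum / incomplete cells",
                  n = nrow(design$data) - nrow(dat))),
         spec = spec),
    class = "ddm_design"
  )
  fit <- fit_ddm_regression(sub, mcmc = mcmc, priors = priors, seed = seed,
                            verbose = verbose)
  structure(
    list(stratum = stratum, fit = fit,
         effect = drift_corrected_effect(fit),
         dropped_participants = dropped),
    class = "stratified_fit"
  )
}

#' @export
print.stratified_fit <- function(x, ...) {
  cat(sprintf("<stratified_fit> stratum: %s (dropped %d participant(s))\n",
              x$stratum, length(x$dropped_participants)))
  print(x$effect)
  invisible(x)
}

#' @export
tidy.stratified_fit <- function(x, ...) x$effect$summary
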