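#' Regression specification for the hierarchical diffusion model
#'
#' Declares which terms enter the trial-wise bound and drift regressions.
#' Confidence terms are factor indicators for the low-confidence and
#' perceived-error categories of the previous trial (lag n) and of the trial
#' after next (lag n+2); high confidence is always the reference and carries
#' no coefficient. An evidence-strength column (coherence or SNR) can enter
#' the drift regression as a per-participant standardized covariate, and an
#' experiment factor can shift the baseline bound when several experiments
#' are fit jointly.
#'
#' @param confidence_bound Include confidence terms on the bound?
#' @param confidence_drift Include confidence terms on the drift?
#' @param drift_covariate Name of the evidence-strength column (e.g.
#'   `"coherence"`) to standardize per participant and add to the drift
#'   regression, or `NULL` for fixed-difficulty designs.
#' @param experiment_col Name of an experiment identifier column; levels
#'   beyond the first get additive baseline-bound indicators.
#' @return A `regression_spec` object.
#' @export
regression_spec <- function(confidence_bound = TRUE, confidence_drift = TRUE,
                            drift_covariate = "coherence",
                            experiment_col = NULL) {
  structure(
    list(confidence_bound = confidence_bound,
         confidence_drift = confidence_drift,
         drift_covariate = drift_covariate,
         experiment_col = experiment_col),
    class = "regression_spec"
  )
}

#' Build the trial-wise design for the regression diffusion model
#'
#' Resolves the lagged confidence categories (previous trial and trial after
#' next, within participant; block boundaries are crossed by default, never
#' participant boundaries), drops edge trials whose lags are undefined, and
#' assembles indicator/covariate matrices for the bound and drift
#' regressions.
#'
#' @param trials Trial table (see [generate_cohort()] / [read_trials()]).
#' @param spec A [regression_spec()].
#' @param lag_across_blocks Resolve lags across block boundaries?
#' @return A `ddm_design`: list with `data` (per usable trial: `participant`,
#'   `rt`, `upper` = response at the correct bound, `conf_prev`,
#'   `conf_next2`, `prev_accuracy`), matrices `Xa` (bound terms) and `Xv`
#'   (drift terms), and `dropped` (edge-trial counts).
#' @examples
#' trials <- generate_cohort(cohort_config(n_participants = 2, n_trials = 50,
#'                                         seed = 3))
#' d <- build_design(trials, regression_spec())
#' head(d$data)
#' @export
build_design <- function(trials, spec = regression_spec(),
                         lag_across_blocks = TRUE) {
  if (!inherits(spec, "regression_spec")) {
    abort("`spec` must be created with `regression_spec()`")
  }
  trials <- ensure_categories(trials)
  grp_vars <- if (lag_across_blocks || !"block" %in% names(trials)) {
    "participant"
  } else {
    c("participant", "block")
  }
  dat <- trials |>
    arrange(.data$participant, .data$trial) |>
    group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    mutate(
      conf_prev = shift_by(.data$confidence_category, 1L),
      conf_next2 = shift_by(.data$confidence_category, -1L),
      prev_accuracy = shift_by(.data$accuracy, 1L)
    ) |>
    ungroup()
  n_all <- nrow(dat)
  dat <- filter(dat, !is.na(.data$conf_prev) & !is.na(.data$conf_next2) &
                  !is.na(.data$rt) & !is.na(.data$accuracy))
  dropped <- n_all - nrow(dat)

  conf_cols <- function(d) {
    cbind(
      low_n = as.numeric(d$conf_prev == "low"),
      pe_n = as.numeric(d$conf_prev == "perceived_error"),
      low_n2 = as.numeric(d$conf_next2 == "low"),
      pe_n2 = as.numeric(d$conf_next2 == "perceived_error")
    )
  }
  Xa <- if (spec$confidence_bound) conf_cols(dat) else
    matrix(numeric(0), nrow(dat), 0)
  if (!is.null(spec$experiment_col)) {
    ex <- factor(dat[[spec$experiment_col]])
    if (nlevels(ex) > 1) {
      for (lv in levels(ex)[-1]) {
        Xa <- cbind(Xa, as.numeric(ex == lv))
        colnames(Xa)[ncol(Xa)] <- paste0("exp_", lv)
      }
    }
  }
  Xv <- if (spec$confidence_drift) conf_cols(dat) else
    matrix(numeric(0), nrow(dat), 0)
  if (!is.null(spec$drift_covariate)) {
    cv <- spec$drift_covariate
    if (!cv %in% names(dat)) {
      abort(sprintf("drift covariate column `%s` not found", cv))
    }
    z <- dat |>
      group_by(.data$participant) |>
      mutate(.z = standardize(.data[[cv]])) |>
      ungroup() |>
      dplyr::pull(".z")
    Xv <- cbind(Xv, evidence = z)
  }

  structure(
    list(
      data = dat |>
        select(dplyr::any_of(c("participant", "block", "trial", "rt",
                               "accuracy", "conf_prev", "conf_next2",
                               "prev_accuracy"))) |>
        mutate(upper = .data$accuracy == 1),
      Xa = Xa, Xv = Xv,
      dropped = tibble(reason = "undefined lag or missing outcome",
                       n = dropped),
      spec = spec
    ),
    class = "ddm_design"
  )
}

#' @export
print.ddm_design <- function(x, ...) {
  cat(sprintf(
    "<ddm_design> %d trials, %d participants; bound terms: %s; drift terms: %s\n",
    nrow(x$data), dplyr::n_distinct(x$data$participant),
    paste(colnames(x$Xa), collapse = ", "),
    paste(colnames(x$Xv), collapse = ", ")
  ))
  cat(sprintf("dropped %d trial(s) with undefined lags\n", sum(x$dropped$n)))
  invisible(x)
}

standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
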