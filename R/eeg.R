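#' Response-locked epoch window specification
#'
#' Conventional single-trial windows: the error-related negativity (ERN) at
#' FCz from -10 to 90 ms around the response, and the error positivity (Pe)
#' at Pz from 250 to 350 ms post-response, both after a 10 Hz low-pass.
#'
#' @param component `"ERN"` or `"Pe"`; sets default electrode and window.
#' @param electrode Electrode label (overrides the component default).
#' @param window Length-2 window in ms relative to the response, start < end.
#' @param lowpass Low-pass cutoff in Hz applied before averaging (zero-phase,
#'   second order); `NA` disables filtering.
#' @return An `epoch_window` object.
#' @export
epoch_window <- function(component = c("ERN", "Pe"), electrode = NULL,
                         window = NULL, lowpass = 10) {
  component <- match.arg(component)
  electrode <- electrode %||% switch(component, ERN = "FCz", Pe = "Pz")
  window <- window %||% switch(component, ERN = c(-10, 90), Pe = c(250, 350))
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be c(start, end) with start < end")
  }
  structure(list(component = component, electrode = electrode,
                 window = window, lowpass = lowpass),
            class = "epoch_window")
}

#' Mean amplitude of an epoch within a time window
#'
#' Applies a zero-phase second-order Butterworth low-pass (if requested) to
#' the whole epoch, then averages the samples whose times fall inside the
#' window. Window endpoints are snapped to the nearest sample and included.
#'
#' @param x Numeric epoch (regularly sampled voltage series, microvolts).
#' @param times_ms Sample times in ms (same length as `x`, equally spaced).
#' @param spec An [epoch_window()], or `NULL` when `window` is given.
#' @param window Length-2 window in ms (overrides `spec`).
#' @param lowpass Low-pass cutoff in Hz; `NA` disables (overrides `spec`).
#' @return Mean amplitude (microvolts).
#' @examples
#' window_mean(c(1, 2, 3, 4, 5), times_ms = 0:4 * 10, window = c(0, 40),
#'             lowpass = NA)
#' @export
window_mean <- function(x, times_ms, spec = NULL, window = NULL,
                        lowpass = NULL) {
  if (!is.null(spec)) {
    window <- window %||% spec$window
    if (is.null(lowpass)) lowpass <- spec$lowpass
  }
  if (is.null(window)) abort("provide `spec` or `window`")
  if (length(x) != length(times_ms)) {
    abort("`x` and `times_ms` must have equal length")
  }
  dts <- diff(times_ms)
  if (any(abs(dts - dts[1]) > 1e-6)) abort("`times_ms` must be equally spaced")
  if (window[1] < min(times_ms) - dts[1] / 2 ||
      window[2] > max(times_ms) + dts[1] / 2) {
    abort("window extends outside the epoch")
  }
  if (!is.null(lowpass) && is.finite(lowpass) && lowpass > 0) {
    fs <- 1000 / dts[1]
    if (lowpass >= fs / 2) abort("low-pass cutoff must be below Nyquist")
    bf <- signal::butter(2, lowpass / (fs / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  # snap endpoints to nearest samples, inclusive
  i0 <- which.min(abs(times_ms - window[1]))
  i1 <- which.min(abs(times_ms - window[2]))
  mean(x[i0:i1])
}

#' Extract single-trial window amplitudes from long-format epochs
#'
#' @param epochs Long tibble with `participant`, `trial`, `electrode`,
#'   `time_ms`, `amplitude`.
#' @param spec An [epoch_window()].
#' @return Tibble `participant`, `trial`, `amplitude`, `component`.
#' @export
extract_amplitudes <- function(epochs, spec) {
  need <- c("participant", "trial", "electrode", "time_ms", "amplitude")
  if (!all(need %in% names(epochs))) {
    abort(paste("`epochs` needs columns:", paste(need, collapse = ", ")))
  }
  sub <- filter(epochs, .data$electrode == spec$electrode)
  if (nrow(sub) == 0) {
    abort(sprintf("electrode `%s` not present in the epochs", spec$electrode))
  }
  sub |>
    group_by(.data$participant, .data$trial) |>
    arrange(.data$time_ms, .by_group = TRUE) |>
    summarise(amplitude = window_mean(.data$amplitude, .data$time_ms, spec),
              .groups = "drop") |>
    mutate(component = spec$component)
}

#' Rank-transform single-trial amplitudes
#'
#' Ascending ranks with average ranks for ties; the robust per-participant
#' predictor used in place of raw single-trial EEG amplitudes. Invariant
#' under any strictly increasing transform of the input.
#'
#' @param x Numeric vector (one participant's amplitudes), length >= 2.
#' @return Ranks 1..n (ties averaged).
#' @examples
#' rank_transform(c(1, 1, 2)) # 1.5 1.5 3
#' @export
rank_transform <- function(x) {
  if (length(x) < 2) abort("need at least 2 trials to rank")
  rank(x, ties.method = "average")
}

#' Regress the ERN out of the Pe
#'
#' Least-squares residuals (with intercept) of trialwise Pe amplitudes on ERN
#' amplitudes, per participant, isolating Pe variance not shared with the
#' ERN. With a zero-variance ERN the centered Pe is returned with a warning.
#'
#' @param pe,ern Paired trialwise amplitudes for one participant.
#' @return Residual Pe values (same length).
#' @examples
#' residualize_pe(pe = c(1, 3, 5), ern = c(0, 1, 2)) # all 0
#' @export
residualize_pe <- function(pe, ern) {
  if (length(pe) != length(ern)) abort("`pe` and `ern` must be paired")
  if (sd(ern) == 0) {
    warn("zero-variance ERN: returning mean-centered Pe")
    return(pe - mean(pe))
  }
  unname(lm.fit(cbind(1, ern), pe)$residuals)
}

#' Equal-count quantile bins of residual Pe amplitudes
#'
#' Rank-based bins per participant, ascending with amplitude (bin 1 = lowest,
#' the regression reference). When `n` is not divisible by `k` the remainder
#' goes to the lower bins first, e.g. 12 values in 5 bins give sizes
#' 3, 3, 2, 2, 2. Ties are resolved by first occurrence, so any monotone
#' relabeling of the amplitudes leaves the assignment unchanged.
#'
#' @param x Numeric vector (one participant), length >= `k`.
#' @param k Number of bins.
#' @return Integer bin labels 1..k.
#' @export
pe_quantile_bins <- function(x, k = 5) {
  n <- length(x)
  if (n < k) abort(sprintf("need at least %d trials for %d bins", k, k))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  bins <- integer(n)
  bins[order(x)] <- rep(seq_len(k), sizes)
  bins
}

#' Regression design with EEG covariates
#'
#' Builds a `ddm_design` in which the next-trial bound and drift vary with
#' single-trial EEG amplitudes at lag n and lag n+2 instead of confidence
#' categories. In continuous mode the predictors are per-participant
#' standardized ranks of the Pe and the ERN (one joint model, so each
#' coefficient captures unique variance); in binned mode they are indicators
#' for quantile bins 2..k of the (optionally ERN-residualized) Pe, bin 1
#' being the reference.
#'
#' @param trials Trial table with `pe_amp` and `ern_amp` columns.
#' @param mode `"continuous"` (Pe + ERN ranks) or `"binned"` (Pe bins).
#' @param k Number of Pe bins in binned mode.
#' @param residualize Regress the ERN out of the Pe before binning?
#' @param lag_across_blocks Resolve lags across block boundaries?
#' @return A `ddm_design` (see [build_design()]).
#' @export
eeg_regression_design <- function(trials, mode = c("continuous", "binned"),
                                  k = 5, residualize = TRUE,
                                  lag_across_blocks = TRUE) {
  mode <- match.arg(mode)
  trials <- ensure_categories(trials)
  if (!all(c("pe_amp", "ern_amp") %in% names(trials))) {
    abort("`trials` needs `pe_amp` and `ern_amp` columns")
  }
  n_missing <- sum(!complete.cases(trials[, c("pe_amp", "ern_amp")]))
  if (n_missing / nrow(trials) > 0.10) {
    warn(sprintf("EEG amplitudes missing on %.1f%% of trials (> 10%%)",
                 100 * n_missing / nrow(trials)))
  }
  if (n_missing > 0) {
    inform(sprintf("dropping %d trial(s) with missing EEG amplitudes",
                   n_missing))
    trials <- filter(trials, !is.na(.data$pe_amp) & !is.na(.data$ern_amp))
  }

  trials <- trials |>
    group_by(.data$participant) |>
    arrange(.data$trial, .by_group = TRUE) |>
    mutate(
      pe_res = if (residualize) residualize_pe(.data$pe_amp, .data$ern_amp)
               else .data$pe_amp
    ) |>
    ungroup()
  if (mode == "continuous") {
    trials <- trials |>
      group_by(.data$participant) |>
      mutate(pe_rank = standardize(rank_transform(.data$pe_amp)),
             ern_rank = standardize(rank_transform(.data$ern_amp))) |>
      ungroup()
    covs <- c("pe_rank", "ern_rank")
  } else {
    trials <- trials |>
      group_by(.data$participant) |>
      mutate(pe_bin = pe_quantile_bins(.data$pe_res, k)) |>
      ungroup()
    for (b in 2:k) trials[[paste0("bin", b)]] <-
        as.numeric(trials$pe_bin == b)
    covs <- paste0("bin", 2:k)
  }

  grp_vars <- if (lag_across_blocks || !"block" %in% names(trials)) {
    "participant"
  } else {
    c("participant", "block")
  }
  dat <- trials |>
    arrange(.data$participant, .data$trial) |>
    group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    mutate(dplyr::across(dplyr::all_of(covs),
                         list(n = ~shift_by(.x, 1L),
                              n2 = ~shift_by(.x, -1L)))) |>
    mutate(prev_accuracy = shift_by(.data$accuracy, 1L),
           conf_prev = shift_by(.data$confidence_category, 1L),
           conf_next2 = shift_by(.data$confidence_category, -1L)) |>
    ungroup()
  lag_cols <- as.vector(outer(covs, c("n", "n2"), paste, sep = "_"))
  n_all <- nrow(dat)
  dat <- dat[complete.cases(dat[, lag_cols]), , drop = FALSE]
  X <- as.matrix(dat[, lag_cols])
  structure(
    list(
      data = dat |>
        select(dplyr::any_of(c("participant", "block", "trial", "rt",
                               "accuracy", "conf_prev", "conf_next2",
                               "prev_accuracy"))) |>
        mutate(upper = .data$accuracy == 1),
      Xa = X, Xv = X,
      dropped = tibble(reason = "undefined EEG lag or missing outcome",
                       n = n_all - nrow(dat)),
      spec = list(mode = mode, k = k, residualize = residualize)
    ),
    class = "ddm_design"
  )
}
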