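#' Collapse six-point confidence ratings into three categories
#'
#' Ratings are in canonical orientation (1 = certainly wrong ... 6 =
#' certainly correct). Ratings 5-6 ("probably/certainly correct") form the
#' high-confidence bin, 3-4 (the two middle "guess" labels) the
#' low-confidence bin, and 1-2 ("probably/certainly wrong") the
#' perceived-error bin.
#'
#' @param rating Integer vector with values in 1..6.
#' @return A factor with levels `high`, `low`, `perceived_error`.
#' @examples
#' bin_confidence(c(6, 3, 1))
#' @export
bin_confidence <- function(rating) {
  if (anyNA(rating) || !all(rating %in% 1:6)) {
    abort("confidence ratings must all be integers in 1..6")
  }
  factor(
    dplyr::case_when(rating >= 5 ~ "high",
                     rating >= 3 ~ "low",
                     TRUE ~ "perceived_error"),
    levels = c("high", "low", "perceived_error")
  )
}

#' Model-free response caution by previous-trial confidence
#'
#' Groups each trial's outcome by the confidence category reported `lag`
#' trials earlier (within participant) and combines the central response time
#' with mean accuracy into the single caution measure `RT * accuracy`,
#' separately per participant and then at the group level. Alongside the
#' primary (trial-n) conditioning it always emits the same statistic
#' conditioned on the category two trials after the predictor (the trial-n+2
#' proxy used to subtract slow performance drift), and the drift-corrected
#' deltas (trial-n minus trial-n+2 deltas relative to high confidence).
#'
#' @param trials Trial table with `participant`, `trial`, `rt`, `accuracy`
#'   and `confidence_category` (or `confidence_rating`).
#' @param lag Positive offset of the predictor trial before the outcome trial
#'   (1 = previous trial).
#' @param rt_center `"median"` (default) or `"mean"` central RT.
#' @return A `caution_summary` object: list with `by_participant` (tibble of
#'   per-participant cells; empty cells are explicit `NA`s, never imputed),
#'   `group` (across-participant means/SDs) and `deltas` (per category vs the
#'   high-confidence reference: trial-n, trial-n+2 and corrected).
#' @examples
#' trials <- generate_cohort(cohort_config(n_participants = 3, n_trials = 60,
#'                                         seed = 2))
#' caution_statistic(trials)
#' @export
caution_statistic <- function(trials, lag = 1,
                              rt_center = c("median", "mean")) {
  rt_center <- match.arg(rt_center)
  fcenter <- if (rt_center == "median") median else mean
  trials <- ensure_categories(trials)
  offs <- c(trial_n = as.integer(lag), trial_n2 = as.integer(lag) - 2L)

  per <- purrr::imap(offs, function(off, ref) {
    trials |>
      group_by(.data$participant) |>
      arrange(.data$trial, .by_group = TRUE) |>
      mutate(prev_cat = shift_by(.data$confidence_category, off)) |>
      ungroup() |>
      filter(!is.na(.data$prev_cat)) |>
      group_by(.data$participant, category = .data$prev_cat) |>
      summarise(
        n = dplyr::n(),
        rt_central = fcenter(.data$rt),
        accuracy = mean(.data$accuracy),
        caution = .data$rt_central * .data$accuracy,
        .groups = "drop"
      ) |>
      tidyr::complete(.data$participant,
                      category = factor(levels(trials$confidence_category),
                                        levels(trials$confidence_category))) |>
      mutate(reference = ref, n = dplyr::coalesce(.data$n, 0L))
  })
  by_participant <- dplyr::bind_rows(per) |>
    dplyr::relocate("reference")

  group <- by_participant |>
    filter(!is.na(.data$caution)) |>
    group_by(.data$reference, .data$category) |>
    summarise(
      n_participants = dplyr::n(),
      rt_central = mean(.data$rt_central),
      accuracy = mean(.data$accuracy),
      caution = mean(.data$caution),
      caution_sd = sd(.data$caution),
      .groups = "drop"
    )

  deltas <- by_participant |>
    group_by(.data$reference, .data$participant) |>
    mutate(
      delta_caution = .data$caution - .data$caution[.data$category == "high"]
    ) |>
    ungroup() |>
    filter(.data$category != "high") |>
    select("reference", "participant", "category", "delta_caution") |>
    tidyr::pivot_wider(names_from = "reference",
                       values_from = "delta_caution") |>
    mutate(corrected = .data$trial_n - .data$trial_n2) |>
    tidyr::pivot_longer(c("trial_n", "trial_n2", "corrected"),
                        names_to = "component", values_to = "delta") |>
    group_by(.data$category, .data$component) |>
    summarise(
      mean = mean(.data$delta, na.rm = TRUE),
      sd = sd(.data$delta, na.rm = TRUE),
      n = sum(!is.na(.data$delta)),
      .groups = "drop"
    )

  structure(
    list(by_participant = by_participant, group = group, deltas = deltas,
         rt_center = rt_center, lag = lag),
    class = "caution_summary"
  )
}

#' @export
print.caution_summary <- function(x, ...) {
  cat(sprintf("<caution_summary> RT center: %s, lag %d\n", x$rt_center, x$lag))
  print(x$group)
  invisible(x)
}

#' @export
tidy.caution_summary <- function(x, ...) x$by_participant

#' Accuracy as a function of the confidence rating
#'
#' Per-participant accuracy for each rating level, pooled across participants
#' (unweighted mean of participant accuracies), with an exact binomial
#' confidence interval and test against chance on the pooled trial counts.
#' Rating levels with no trials are reported as missing, not zero.
#'
#' @param trials Trial table with `participant`, `accuracy`,
#'   `confidence_rating` (canonical orientation).
#' @param conf_level Confidence level of the binomial interval.
#' @return Tibble with one row per rating level 1..6.
#' @export
accuracy_by_confidence <- function(trials, conf_level = 0.95) {
  if (!all(c("participant", "accuracy", "confidence_rating") %in%
           names(trials))) {
    abort("`trials` needs participant, accuracy, confidence_rating columns")
  }
  per <- trials |>
    group_by(.data$participant, rating = .data$confidence_rating) |>
    summarise(acc = mean(.data$accuracy), n = dplyr::n(), .groups = "drop")
  pooled <- trials |>
    group_by(rating = .data$confidence_rating) |>
    summarise(k = sum(.data$accuracy), n = sum(!is.na(.data$accuracy)),
              .groups = "drop")
  res <- per |>
    group_by(.data$rating) |>
    summarise(accuracy = mean(.data$acc),
              n_participants = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(pooled, by = "rating")
  bt <- purrr::map(seq_len(nrow(res)), function(i) {
    b <- binom.test(res$k[i], res$n[i], p = 0.5, conf.level = conf_level)
    tibble(acc_pooled = res$k[i] / res$n[i],
           ci_lo = b$conf.int[1], ci_hi = b$conf.int[2],
           p_vs_chance = b$p.value)
  })
  res <- dplyr::bind_cols(res, dplyr::bind_rows(bt)) |>
    mutate(differs_from_chance = .data$p_vs_chance < 1 - conf_level)
  tidyr::complete(res, rating = 1:6)
}

#' Spectral slope of a behavioral time series
#'
#' Least-squares slope of log power versus log frequency, the standard
#' scale-free ("1/f") diagnostic for slow fluctuations in trial series such
#' as RTs or confidence ratings. Uses the raw periodogram (DC excluded) with
#' frequencies averaged within log-spaced bins before the linear fit.
#'
#' @param series Numeric per-trial series, length >= 64.
#' @param detrend Remove a linear trend first (the mean is always removed).
#' @param n_bins Number of log-frequency bins for the fit.
#' @param na_action `"error"` (default), `"drop"` missing values, or
#'   `"interpolate"` them linearly; drops/fills are reported via a message.
#' @return The slope (a negative value indicates long-range, scale-free
#'   autocorrelation), with the binned spectrum in attribute `"spectrum"`.
#' @examples
#' spectral_slope(rnorm(256))
#' @export
spectral_slope <- function(series, detrend = TRUE, n_bins = 12,
                           na_action = c("error", "drop", "interpolate")) {
  na_action <- match.arg(na_action)
  if (anyNA(series)) {
    n_missing <- sum(is.na(series))
    if (na_action == "error") {
      abort("`series` contains missing values; set `na_action`")
    } else if (na_action == "drop") {
      series <- series[!is.na(series)]
    } else {
      idx <- seq_along(series)
      series <- approx(idx[!is.na(series)], series[!is.na(series)],
                       xout = idx, rule = 2)$y
    }
    inform(sprintf("spectral_slope: handled %d missing value(s) by %s",
                   n_missing, na_action))
  }
  n <- length(series)
  if (n < 64) abort("`series` must have at least 64 observations")
  if (sd(series) == 0) abort("spectral slope is undefined for a constant series")
  x <- series - mean(series)
  if (detrend) x <- stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
  nf <- floor((n - 1) / 2)
  f <- seq_len(nf) / n
  pgram <- (Mod(fft(x))^2 / n)[2:(nf + 1)]
  keep <- pgram > 0
  f <- f[keep]; pgram <- pgram[keep]
  edges <- exp(seq(log(min(f)) - 1e-9, log(max(f)) + 1e-9,
                   length.out = n_bins + 1))
  bin <- cut(f, edges, labels = FALSE, include.lowest = TRUE)
  lf <- tapply(log(f), bin, mean)
  lp <- tapply(log(pgram), bin, mean)
  fit <- stats::lm.fit(cbind(1, as.numeric(lf)), as.numeric(lp))
  slope <- unname(fit$coefficients[2])
  attr(slope, "spectrum") <- tibble(log_f = as.numeric(lf),
                                    log_power = as.numeric(lp))
  slope
}

# --- internal helpers -------------------------------------------------------

# lag for positive k, lead for negative k
shift_by <- function(x, k) {
  if (k >= 0) dplyr::lag(x, k) else dplyr::lead(x, -k)
}

ensure_categories <- function(trials) {
  need <- c("participant", "trial", "rt", "accuracy")
  if (!all(need %in% names(trials))) {
    abort(paste("trial table must contain columns:",
                paste(need, collapse = ", ")))
  }
  if (!"confidence_category" %in% names(trials)) {
    if (!"confidence_rating" %in% names(trials)) {
      abort("need `confidence_category` or `confidence_rating`")
    }
    trials$confidence_category <- bin_confidence(trials$confidence_rating)
  }
  if (!is.factor(trials$confidence_category)) {
    trials$confidence_category <- factor(
      trials$confidence_category,
      levels = c("high", "low", "perceived_error")
    )
  }
  trials
}
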