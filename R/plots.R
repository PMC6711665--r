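#' Plot the model-free caution summary
#'
#' Group-level central RT, accuracy and their product (caution) on the trial
#' after each confidence category, for the trial-n and trial-n+2
#' conditionings.
#'
#' @param object A `caution_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.caution_summary <- function(object, ...) {
  dat <- object$group |>
    tidyr::pivot_longer(c("rt_central", "accuracy", "caution"),
                        names_to = "measure", values_to = "value") |>
    mutate(measure = factor(.data$measure,
                            c("rt_central", "accuracy", "caution"),
                            c("central RT (s)", "accuracy",
                              "caution (RT x accuracy)")))
  ggplot(dat, aes(x = .data$category, y = .data$value,
                  group = .data$reference, color = .data$reference)) +
    geom_point(position = position_dodge(width = 0.3)) +
    geom_line(position = position_dodge(width = 0.3)) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = "confidence on the predictor trial", y = NULL,
         color = "conditioned on",
         title = "Response caution by previous confidence") +
    theme_minimal()
}

#' Plot drift-corrected sequential effects
#'
#' Posterior densities of the corrected (lag-n minus lag-n+2) group-level
#' bound and drift changes per predictor category, centered on the
#' high-confidence (or reference-bin) baseline at zero.
#'
#' @param object A `sequential_effect`.
#' @param component Which component to show (`"corrected"`, `"raw_n"`,
#'   `"raw_n2"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sequential_effect <- function(object, component = "corrected", ...) {
  dd <- purrr::imap_dfr(object$draws, function(d, stem) {
    tibble(
      parameter = if (startsWith(stem, "a_")) "bound" else "drift",
      category = sub("^[av]_", "", stem),
      value = d[[component]]
    )
  })
  ggplot(dd, aes(x = .data$value, fill = .data$category)) +
    geom_density(alpha = 0.5) +
    geom_vline(xintercept = 0, linetype = 2) +
    facet_wrap(~parameter, scales = "free") +
    labs(x = sprintf("group posterior (%s), delta vs reference", component),
         y = "density",
         title = "Sequential modulation of decision parameters") +
    theme_minimal()
}

#' Trace plot of group-level parameters
#'
#' @param object A `ddm_fit`.
#' @param parameters Parameter names (default: all group-level means).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ddm_fit <- function(object, parameters = NULL, ...) {
  parameters <- parameters %||% object$par_names
  dd <- as_tibble(object$mu[, parameters, drop = FALSE]) |>
    mutate(chain = factor(object$chain),
           iter = stats::ave(object$chain, object$chain, FUN = seq_along)) |>
    tidyr::pivot_longer(-c("chain", "iter"), names_to = "parameter",
                        values_to = "value")
  ggplot(dd, aes(x = .data$iter, y = .data$value, color = .data$chain)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "kept iteration", y = "group-level draw",
         title = "MCMC traces") +
    theme_minimal()
}

#' Plot accuracy against the confidence rating
#'
#' @param acc_table Output of [accuracy_by_confidence()].
#' @return A ggplot object.
#' @export
plot_accuracy_by_confidence <- function(acc_table) {
  ggplot(filter(acc_table, !is.na(.data$accuracy)),
         aes(x = .data$rating, y = .data$acc_pooled)) +
    geom_hline(yintercept = 0.5, linetype = 2) +
    geom_pointrange(aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    geom_line() +
    scale_x_continuous(breaks = 1:6) +
    labs(x = "confidence rating (1 = certainly wrong, 6 = certainly correct)",
         y = "accuracy", title = "Rating-predicted accuracy") +
    theme_minimal()
}
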