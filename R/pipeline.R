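#' Configuration of an end-to-end analysis run
#'
#' @param generator A [cohort_config()] used to simulate the cohort, or
#'   `NULL` when `input` is given.
#' @param input Path to a trial table read with [read_trials()].
#' @param stages Stages to run, in order, among `"simulate"`, `"caution"`,
#'   `"fit"`, `"sequential"`, `"eeg"`.
#' @param spec A [regression_spec()] for the confidence fit.
#' @param mcmc An [mcmc_control()].
#' @param priors A [prior_control()].
#' @param seed Integer seed (mandatory; governs every stochastic step).
#' @param out_dir Output directory (created if needed).
#' @param null_cohort Override the generator with a null-coupling cohort
#'   (all bound updates zero), used for falsification runs.
#' @return A `run_config` object.
#' @export
run_config <- function(generator = cohort_config(), input = NULL,
                       stages = c("simulate", "caution", "fit", "sequential"),
                       spec = regression_spec(),
                       mcmc = mcmc_control(), priors = prior_control(),
                       seed = 1, out_dir = tempfile("boundshift_run_"),
                       null_cohort = FALSE) {
  if (is.null(seed)) abort("a seed is mandatory")
  if (is.null(generator) && is.null(input)) {
    abort("provide a `generator` config or an `input` path")
  }
  if (null_cohort && !is.null(generator)) {
    generator$bound_update <- c(high = 0, low = 0, perceived_error = 0)
    generator$bound_coupling <- "confidence"
  }
  structure(
    list(generator = generator, input = input, stages = stages, spec = spec,
         mcmc = mcmc, priors = priors, seed = seed, out_dir = out_dir,
         null_cohort = null_cohort),
    class = "run_config"
  )
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, force = TRUE, auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages: simulate (or read) the trial table, compute
#' the model-free caution summary, fit the hierarchical regression diffusion
#' model, derive the drift-corrected sequential effects, and (when EEG
#' amplitudes are present) the continuous-mode EEG fit. Each output file
#' carries the configuration hash and seed as a comment header, so a recorded
#' run can be reproduced exactly. A machine-readable summary (JSON) with drop
#' counts, R-hat range and the corrected effects is always written.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress?
#' @return A list (class `pipeline_result`) with the output paths, the trial
#'   table, fitted objects and the summary list.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "run_config")) abort("`config` must be run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- sprintf("config_hash=%s seed=%d", hash, config$seed)
  paths <- list()
  say <- function(...) if (verbose) inform(sprintf(...))
  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", stage, conditionMessage(e)))
    })
  }
  summary <- list(config_hash = hash, seed = config$seed,
                  null_cohort = config$null_cohort)

  # --- trials ---------------------------------------------------------------
  trials <- stage_guard("simulate", {
    if (!is.null(config$input)) {
      read_trials(config$input)
    } else {
      gen <- config$generator
      gen$seed <- config$seed
      generate_cohort(gen)
    }
  })
  if ("simulate" %in% config$stages) {
    paths$trials <- file.path(config$out_dir, "trials.tsv")
    write_trials(trials, paths$trials, header = hdr)
    say("wrote %s", paths$trials)
  }
  summary$n_trials <- nrow(trials)
  summary$n_participants <- dplyr::n_distinct(trials$participant)

  caution <- fit <- effect <- eeg_fit <- eeg_effect <- NULL

  if ("caution" %in% config$stages) {
    caution <- stage_guard("caution", caution_statistic(trials))
    paths$caution <- file.path(config$out_dir, "caution_group.tsv")
    write_trials(caution$group, paths$caution, header = hdr)
    paths$caution_participant <- file.path(config$out_dir,
                                           "caution_by_participant.tsv")
    write_trials(caution$by_participant, paths$caution_participant,
                 header = hdr)
    say("wrote caution summaries")
  }

  if ("fit" %in% config$stages) {
    fit <- stage_guard("fit", {
      design <- build_design(trials, config$spec)
      fit_ddm_regression(design, mcmc = config$mcmc, priors = config$priors,
                         seed = config$seed)
    })
    paths$draws <- file.path(config$out_dir, "draws_group.csv")
    draws_long <- as_tibble(fit$mu) |>
      mutate(chain = fit$chain,
             iter = stats::ave(fit$chain, fit$chain, FUN = seq_along)) |>
      tidyr::pivot_longer(-c("chain", "iter"), names_to = "parameter",
                          values_to = "value")
    writeLines(paste0("# ", hdr), paths$draws)
    readr::write_csv(draws_long, paths$draws, append = TRUE,
                     col_names = TRUE)
    paths$fit_report <- file.path(config$out_dir, "fit_report.tsv")
    write_trials(tidy(fit), paths$fit_report, header = hdr)
    summary$rhat_range <- range(fit$rhat)
    summary$invalid_rate <- fit$invalid_rate
    summary$dropped_edge_trials <- sum(fit$design_info$dropped$n)
    say("fit done (max R-hat %.3f)", max(fit$rhat))
  }

  if ("sequential" %in% config$stages) {
    if (is.null(fit)) abort("[stage sequential] requires the fit stage")
    effect <- stage_guard("sequential", drift_corrected_effect(fit))
    paths$sequential <- file.path(config$out_dir, "sequential_effects.tsv")
    write_trials(effect$summary, paths$sequential, header = hdr)
    summary$effects <- effect$summary |>
      filter(.data$component == "corrected") |>
      mutate(covers_zero = .data$ci_lo <= 0 & .data$ci_hi >= 0) |>
      select("parameter", "category", "mean", "ci_lo", "ci_hi", "p",
             "covers_zero")
    say("wrote sequential effects")
  }

  if ("eeg" %in% config$stages &&
      all(c("pe_amp", "ern_amp") %in% names(trials))) {
    eeg_fit <- stage_guard("eeg", {
      d <- eeg_regression_design(trials, mode = "continuous")
      fit_ddm_regression(d, mcmc = config$mcmc, priors = config$priors,
                         seed = config$seed)
    })
    eeg_effect <- drift_corrected_effect(eeg_fit)
    paths$eeg <- file.path(config$out_dir, "eeg_effects.tsv")
    write_trials(eeg_effect$summary, paths$eeg, header = hdr)
    say("wrote EEG effects")
  }

  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  structure(
    list(paths = paths, trials = trials, caution = caution, fit = fit,
         effect = effect, eeg_fit = eeg_fit, eeg_effect = eeg_effect,
         summary = summary),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n outputs:\n")
  for (p in x$paths) cat("  ", p, "\n")
  invisible(x)
}
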