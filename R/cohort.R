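#' Configuration for the synthetic cohort generator
#'
#' Defines the generative conditions for a multi-participant perceptual
#' decision cohort: diffusion parameters per participant, a confidence report
#' produced by post-decisional evidence accumulation mapped onto a six-point
#' scale, trial-to-trial coupling of the decision bound to the previous
#' trial's confidence category (or to the previous trial's Pe-like
#' amplitude), slow scale-free modulation of drift rate, and
#' confidence-correlated EEG-like single-trial amplitudes.
#'
#' The defaults emulate a random-dot motion experiment: five coherence levels
#' \{0, .05, .10, .20, .40\}, 330 rated trials per participant in 6 blocks,
#' group bound separation near 2, non-decision time near 0.38 s, and bound
#' increments after low-confidence (+0.08) and perceived-error (+0.26)
#' trials. Confidence thresholds are calibrated so the high / low /
#' perceived-error category mix is roughly 58% / 35% / 7%.
#'
#' @param n_participants Number of participants.
#' @param n_trials Rated trials per participant.
#' @param n_blocks Blocks per participant (trials are contiguous in blocks).
#' @param coherence_levels Evidence strengths, all `>= 0`, sampled uniformly
#'   per trial. A 0 level has no objectively correct answer; accuracy is then
#'   assigned by seeded random designation and flagged (`pseudo_accuracy`).
#' @param drift_gain Group mean of the linear coherence-to-drift gain
#'   (`v = gain * coherence`), and `drift_gain_sd` its between-participant SD.
#' @param base_bound,base_bound_sd Group mean/SD of the baseline bound
#'   separation `a0` (model units, `sigma = 1` convention).
#' @param t_er,t_er_sd Group mean/SD of non-decision time (s).
#' @param bound_update Named vector of bound increments added on the trial
#'   after each confidence category, `c(high = , low = , perceived_error = )`.
#'   The high-confidence increment is the reference and should be 0.
#' @param bound_update_sd Between-participant SD of the non-reference
#'   increments.
#' @param bound_coupling `"confidence"` couples the next-trial bound to the
#'   previous confidence category via `bound_update`; `"pe"` couples it
#'   linearly to the previous trial's Pe-like amplitude; `"accuracy"` adds the
#'   perceived-error increment after objective errors regardless of
#'   confidence (a discriminating counterexample for stratified analyses);
#'   `"none"` fixes it.
#' @param pe_bound_gain Bound change (model units) per nominal SD of Pe
#'   amplitude when `bound_coupling = "pe"`.
#' @param postdecision_duration Seconds of continued accumulation after the
#'   choice that feed the confidence judgment.
#' @param confidence_thresholds Five strictly increasing cutpoints on the
#'   post-decisional confidence variable, mapping it to ratings 1..6.
#' @param confidence_noise SD of rating noise added to the confidence
#'   variable.
#' @param slow_drift List `list(beta =, amplitude =, bound_amplitude =)`:
#'   spectral exponent (`<= 0`) and log-scale amplitudes of the multiplicative
#'   gain series applied to drift rate (`amplitude`) and, optionally, to the
#'   baseline bound (`bound_amplitude`, default 0). Both gains are driven by
#'   the same underlying slow state, as a shared arousal/motivation state
#'   would be. `amplitude = 0` disables the modulation entirely.
#' @param eeg List with `pe_gain`, `pe_noise`, `ern_gain`, `ern_noise`:
#'   linear loadings of Pe-like and ERN-like amplitudes (arbitrary microvolt
#'   scale) on the standardized post-decisional error evidence, plus
#'   independent noise SDs.
#' @param block_reset Reset the bound carry-over at block starts? By default
#'   sequential state crosses block but never participant boundaries.
#' @param rt_max Censoring cap (s) on the decision simulator.
#' @param dt Euler-Maruyama step (s) for trial simulation.
#' @param seed Integer seed; the whole cohort is reproducible given the seed.
#'
#' @return A `cohort_config` object (validated list).
#' @export
cohort_config <- function(n_participants = 25,
                          n_trials = 330,
                          n_blocks = 6,
                          coherence_levels = c(0, .05, .1, .2, .4),
                          drift_gain = 3.5,
                          drift_gain_sd = 0.5,
                          base_bound = 2.0,
                          base_bound_sd = 0.3,
                          t_er = 0.38,
                          t_er_sd = 0.09,
                          bound_update = c(high = 0, low = 0.08,
                                           perceived_error = 0.26),
                          bound_update_sd = 0.03,
                          bound_coupling = c("confidence", "pe", "accuracy",
                                             "none"),
                          pe_bound_gain = 0.15,
                          postdecision_duration = 1.0,
                          confidence_thresholds = c(-1.07, -0.40, 0.43, 1.10, 1.83),
                          confidence_noise = 0.25,
                          slow_drift = list(beta = -1, amplitude = 0.25),
                          eeg = list(pe_gain = 3, pe_noise = 4,
                                     ern_gain = 1.5, ern_noise = 6.7),
                          block_reset = FALSE,
                          rt_max = 20,
                          dt = 1e-3,
                          seed = 1) {
  bound_coupling <- match.arg(bound_coupling)
  if (length(confidence_thresholds) != 5 ||
      any(diff(confidence_thresholds) <= 0)) {
    abort("`confidence_thresholds` must be 5 strictly increasing cutpoints")
  }
  if (any(coherence_levels < 0)) abort("coherence levels must be >= 0")
  if (!all(c("high", "low", "perceived_error") %in% names(bound_update))) {
    abort("`bound_update` needs named entries high, low, perceived_error")
  }
  if (any(!is.finite(bound_update))) abort("`bound_update` must be finite")
  if (!is.list(slow_drift) || is.null(slow_drift$beta) ||
      is.null(slow_drift$amplitude)) {
    abort("`slow_drift` must be list(beta =, amplitude =)")
  }
  slow_drift$bound_amplitude <- slow_drift$bound_amplitude %||% 0
  if (slow_drift$beta > 0) abort("slow-drift spectral exponent must be <= 0")
  if (slow_drift$amplitude < 0 || slow_drift$bound_amplitude < 0) {
    abort("slow-drift amplitudes must be >= 0")
  }
  if (n_trials < n_blocks) abort("`n_trials` must be at least `n_blocks`")
  structure(
    list(
      n_participants = n_participants, n_trials = n_trials,
      n_blocks = n_blocks, coherence_levels = coherence_levels,
      drift_gain = drift_gain, drift_gain_sd = drift_gain_sd,
      base_bound = base_bound, base_bound_sd = base_bound_sd,
      t_er = t_er, t_er_sd = t_er_sd,
      bound_update = bound_update[c("high", "low", "perceived_error")],
      bound_update_sd = bound_update_sd,
      bound_coupling = bound_coupling, pe_bound_gain = pe_bound_gain,
      postdecision_duration = postdecision_duration,
      confidence_thresholds = confidence_thresholds,
      confidence_noise = confidence_noise,
      slow_drift = slow_drift, eeg = eeg,
      block_reset = block_reset, rt_max = rt_max, dt = dt, seed = seed
    ),
    class = "cohort_config"
  )
}

#' Multiplicative slow performance-drift gain series
#'
#' Generates a positive gain series whose log has a `1/f^|beta|` power
#' spectrum, by spectral synthesis (Gaussian spectral coefficients with
#' amplitudes `f^(beta/2)`, random phases). The log-series is standardized,
#' scaled by `amplitude`, exponentiated, and normalized to mean exactly 1.
#'
#' @param n_trials Length of the series.
#' @param beta Spectral exponent (`<= 0`); 0 gives white modulation.
#' @param amplitude SD of the log-gain; 0 returns a series of exact 1s.
#' @param seed Optional integer seed; `NULL` uses the session RNG.
#' @return Numeric vector of positive gains with mean 1.
#' @examples
#' g <- apply_slow_drift(1024, beta = -0.5, amplitude = 0.3, seed = 1)
#' mean(g)
#' @export
apply_slow_drift <- function(n_trials, beta = -1, amplitude = 0.25,
                             seed = NULL) {
  if (beta > 0) abort("`beta` must be <= 0")
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  if (n_trials < 2) abort("`n_trials` must be at least 2")
  if (amplitude == 0) return(rep(1, n_trials))
  if (!is.null(seed)) set.seed(seed)
  slow_gain(amplitude, slow_state(n_trials, beta))
}

# standardized 1/f^|beta| latent state by spectral synthesis
slow_state <- function(n, beta) {
  nf <- floor(n / 2)
  f <- seq_len(nf) / n
  amp <- f^(beta / 2)
  co <- amp * complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1)] <- co
  if (n %% 2 == 0) spec[nf + 1] <- complex(real = sqrt(2) * Re(co[nf]))
  spec[n:(n - nf + 2)] <- Conj(co[seq_len(nf - 1)])
  x <- Re(fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

slow_gain <- function(amplitude, state) {
  if (amplitude == 0) return(rep(1, length(state)))
  g <- exp(amplitude * state)
  g / mean(g)
}

#' Confidence rating from post-decisional evidence
#'
#' Maps post-decisional evidence onto a six-point confidence rating in the
#' choice-conditional frame (6 = certain the choice was correct, 1 = certain
#' it was wrong). The confidence variable is the distance already travelled
#' to the chosen bound (`bound_offset`, positive) plus the signed
#' post-decisional increment toward the chosen option, plus rating noise; it
#' is cut by the five ordered thresholds.
#'
#' @param extra_evidence Signed post-decisional evidence accumulated toward
#'   the chosen option (negative values favor the unchosen option).
#' @param bound_offset Distance from start point to the chosen bound at
#'   commitment (`a/2` for an unbiased process); recycled.
#' @param thresholds Five strictly increasing cutpoints.
#' @param noise_sd SD of rating noise (drawn from the session RNG).
#' @return Integer ratings in 1..6.
#' @examples
#' postdecision_confidence(c(2, -3), bound_offset = 1,
#'                         thresholds = c(-1, -0.5, 0, 0.5, 1))
#' @export
postdecision_confidence <- function(extra_evidence, bound_offset,
                                    thresholds, noise_sd = 0) {
  if (length(thresholds) != 5 || any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be 5 strictly increasing cutpoints")
  }
  cv <- bound_offset + extra_evidence
  if (noise_sd > 0) cv <- cv + rnorm(length(cv), 0, noise_sd)
  as.integer(findInterval(cv, thresholds) + 1L)
}

#' Generate a synthetic cohort of behavioral (and EEG-like) trials
#'
#' Simulates every participant trial by trial: the drift rate is
#' `gain_j * coherence_t * slow_gain_t`, the bound separation is the
#' participant baseline plus the configured coupling to the previous trial's
#' confidence category (or Pe amplitude), choices and response times come
#' from the diffusion simulator, the confidence rating from continued
#' post-decisional accumulation of the same drift, and Pe-like / ERN-like
#' amplitudes load on the standardized post-decisional error evidence.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble of trial records with columns `participant`, `block`,
#'   `trial`, `coherence`, `stimulus`, `choice`, `accuracy`, `rt`,
#'   `confidence_rating`, `confidence_category`, `pe_amp`, `ern_amp`, the
#'   generator ground truth `true_a`, `true_v`, `true_ter`, `slow_gain`, and
#'   the `pseudo_accuracy` flag for zero-evidence trials.
#' @examples
#' trials <- generate_cohort(cohort_config(n_participants = 2, n_trials = 40,
#'                                         seed = 7))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created with `cohort_config()`")
  }
  set.seed(config$seed)
  J <- config$n_participants
  n <- config$n_trials
  tau <- config$postdecision_duration
  upd <- config$bound_update
  eeg <- config$eeg
  # nominal Pe scale used to express the pe->bound coupling per SD
  pe_scale <- sqrt(eeg$pe_gain^2 + eeg$pe_noise^2)
  block_of <- sort(rep_len(seq_len(config$n_blocks), n))

  out <- vector("list", J)
  n_censored <- 0L
  for (j in seq_len(J)) {
    a0 <- max(0.6, rnorm(1, config$base_bound, config$base_bound_sd))
    ter <- max(0.05, rnorm(1, config$t_er, config$t_er_sd))
    gain <- max(0.5, rnorm(1, config$drift_gain, config$drift_gain_sd))
    upd_j <- upd + c(0, rnorm(2, 0, config$bound_update_sd))
    sdrift <- config$slow_drift
    no_mod <- sdrift$amplitude == 0 &&
      (sdrift$bound_amplitude %||% 0) == 0
    state <- if (no_mod) numeric(n) else slow_state(n, sdrift$beta)
    g <- slow_gain(sdrift$amplitude, state)
    gb <- slow_gain(sdrift$bound_amplitude %||% 0, state)
    coh <- sample(config$coherence_levels, n, replace = TRUE)
    stim <- sample(c("left", "right"), n, replace = TRUE)
    # for zero-evidence trials the "correct" side is a random designation
    pseudo <- coh == 0
    sim_seeds <- runif(n) * 2^31
    zpost <- rnorm(n, 0, sqrt(tau))
    znoise <- rnorm(n, 0, config$confidence_noise)
    zpe <- rnorm(n, 0, eeg$pe_noise)
    zern <- rnorm(n, 0, eeg$ern_noise)

    a_t <- numeric(n); v_t <- numeric(n); rt <- numeric(n)
    acc <- integer(n); rating <- integer(n); cens <- logical(n)
    pe <- numeric(n); ern <- numeric(n); choice <- character(n)

    prev_cat <- NA_character_
    prev_pe <- NA_real_
    prev_acc <- NA_real_
    for (t in seq_len(n)) {
      new_seq <- t == 1 ||
        (config$block_reset && block_of[t] != block_of[t - 1])
      a_base <- a0 * gb[t]
      a <- if (new_seq || config$bound_coupling == "none") {
        a_base
      } else if (config$bound_coupling == "confidence") {
        a_base + unname(upd_j[prev_cat])
      } else if (config$bound_coupling == "accuracy") {
        a_base + (1 - prev_acc) * unname(upd_j["perceived_error"])
      } else {
        a_base + config$pe_bound_gain * prev_pe / pe_scale
      }
      if (is.na(a) || a <= 0) {
        abort("configuration produced a non-positive bound separation")
      }
      v <- gain * coh[t] * g[t]
      s <- .simulate_ddm_cpp(1L, a, v, ter, 0.5, 1, config$dt,
                             config$rt_max, TRUE, sim_seeds[t])
      if (s$censored[1]) {
        cens[t] <- TRUE
        n_censored <- n_censored + 1L
        # keep sequential state defined: treat as a guess with no evidence
        acc[t] <- NA_integer_
        prev_cat <- "low"; prev_pe <- 0; prev_acc <- 1
        next
      }
      correct <- isTRUE(s$upper[1])
      acc[t] <- as.integer(correct)
      choice[t] <- if (correct) stim[t] else setdiff(c("left", "right"), stim[t])
      rt[t] <- s$rt[1]
      a_t[t] <- a; v_t[t] <- v
      # continued accumulation toward the chosen option for tau seconds
      e_post <- (if (correct) v else -v) * tau + zpost[t]
      rating[t] <- postdecision_confidence(e_post + znoise[t], a / 2,
                                           config$confidence_thresholds,
                                           noise_sd = 0)
      # standardized error evidence drives the EEG-like amplitudes
      eps <- -e_post / sqrt(tau)
      pe[t] <- eeg$pe_gain * eps + zpe[t]
      ern[t] <- eeg$ern_gain * eps + zern[t]
      prev_cat <- as.character(bin_confidence(rating[t]))
      prev_pe <- pe[t]
      prev_acc <- acc[t]
    }

    out[[j]] <- tibble(
      participant = j, block = block_of, trial = seq_len(n),
      coherence = coh, stimulus = stim, choice = choice,
      accuracy = acc, rt = rt, confidence_rating = rating,
      pe_amp = pe, ern_amp = ern,
      true_a = a_t, true_v = v_t, true_ter = ter, slow_gain = g,
      pseudo_accuracy = pseudo, censored = cens
    )
  }
  trials <- dplyr::bind_rows(out)
  if (n_censored > 0) {
    warn(sprintf("dropped %d censored trial(s) that failed to absorb within %g s",
                 n_censored, config$rt_max))
    trials <- dplyr::filter(trials, !.data$censored)
  }
  trials <- dplyr::select(trials, -"censored")
  trials$confidence_category <- bin_confidence(trials$confidence_rating)
  attr(trials, "cohort_config") <- config
  trials
}
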