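# shared fixtures, built once per test run

.fixtures <- new.env()

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(
      cohort_config(n_participants = 8, n_trials = 330, seed = 301)
    )
  }
  .fixtures$cohort
}

# small joint fit with the default confidence design, reused across tests
fixture_fit <- function() {
  if (is.null(.fixtures$fit)) {
    trials <- generate_cohort(
      cohort_config(n_participants = 8, n_trials = 260, seed = 302)
    )
    d <- build_design(trials, regression_spec())
    .fixtures$fit <- suppressWarnings(
      fit_ddm_regression(d, mcmc = mcmc_control(n_chains = 2,
                                                n_samples = 600),
                         seed = 11)
    )
  }
  .fixtures$fit
}

# tiny hand-made trial table
toy_trials <- function(ratings, rt = NULL, accuracy = NULL,
                       participant = 1) {
  n <- length(ratings)
  tibble::tibble(
    participant = participant,
    trial = seq_len(n),
    rt = rt %||% rep(1, n),
    accuracy = accuracy %||% rep(1L, n),
    confidence_rating = ratings
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
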