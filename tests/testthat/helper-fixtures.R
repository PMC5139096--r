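# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# trial-scale packaged synthetic fixture (full arm sizes, scenario defaults)
fixture_inputs <- function() {
  if (is.null(.fixture_env$full)) {
    .fixture_env$full <- build_model_inputs(trial_scenario())
  }
  .fixture_env$full
}

# reduced-scale inputs for unit tests that only need plumbing
small_scenario <- function() {
  trial_scenario(arm_sizes = c(none = 20000, MMS = 10000, USS = 10000))
}

small_inputs <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- build_model_inputs(small_scenario(), seed = 11)
  }
  .fixture_env$small
}

# a plain transition schedule + payoffs for engine-level tests
toy_schedule <- function(horizon = 40, screened = TRUE, seed = NULL,
                         oc_death = NULL, incidence = NULL, other = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(oc_death)) oc_death <- runif(horizon, 0, 0.004) * seq_len(horizon) / horizon
  if (is.null(incidence)) incidence <- runif(horizon, 0.001, 0.01)
  if (is.null(other)) other <- pmin(0.002 * 1.08^(seq_len(horizon)), 0.5)
  build_schedule(oc_death, incidence, other, screened = screened,
                 n_screens = 7)
}

toy_payoffs <- function(strategy = "MMS", ...) {
  build_payoffs(strategy, parameter_means(), options = model_options(...))
}
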