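# Shared fixtures, built lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

small_cfg <- function(n_trials = 2, trial_duration = 8) {
  path_config(n_trials = n_trials, trial_duration = trial_duration)
}

# Target trace re-used as a carrier for hand-built cursor signals.
base_target <- function(duration = 10, seed = 42) {
  fixture(sprintf("target_%d_%d", duration, seed), function() {
    target_trace(path_config(n_trials = 1, trial_duration = duration),
                 seed = seed)
  })
}

# Session where the cursor is the target plus a supplied offset signal.
session_with_cursor <- function(offset_x = 0, offset_y = 0, duration = 10,
                                force = 1, seed = 42) {
  tt <- base_target(duration, seed)
  s <- tibble::tibble(
    trial = tt$trial, t = tt$t,
    target_x = tt$target_x, target_y = tt$target_y,
    cursor_x = tt$target_x + offset_x, cursor_y = tt$target_y + offset_y,
    force = force
  )
  attr(s, "sampling_rate") <- 100
  s
}

# A small mixed cohort with epoch metrics, shared by classifier tests.
cohort_metrics <- function() {
  fixture("cohort_metrics", function() {
    coh <- simulate_cohort(4, 3, 3, small_cfg(3, 10), seed = 101)
    compute_metrics(coh)
  })
}

# Noise-free deterministic profiles for closed-form checks.
clean_profile <- function(label, ...) {
  subject_profile(label, noise_sd = 0, force_var = 0, ...)
}
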