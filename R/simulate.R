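#' Synthetic subject profiles
#'
#' A `subject_profile` parameterizes the generative model that stands in for
#' a human subject tracking the target: a first-order pursuit controller plus
#' additive tremor, positional noise, and a stylus-force channel.
#'
#' Built-in profiles:
#' * `control` — no tremor, no lag, unit gain, minimal noise.
#' * `pd` — heterogeneous impairment: mild 5 Hz tremor, reaction lag,
#'   reduced gain, elevated noise, slowed movement (displacement cap), and
#'   elevated force variance. Mirrors the clinical heterogeneity of
#'   parkinsonian motor dysfunction.
#' * `et` — tremor-dominant: large 6 Hz action tremor with every other
#'   component at control level, the essential-tremor phenotype.
#'
#' `severity` scales all pathological components jointly: at `severity = 0`
#' every parameter collapses to its control baseline; at `severity = 1` the
#' profile's nominal values apply; larger values amplify them (with
#' `speed_scale` and `tracking_gain` floored just above zero).
#'
#' @param label One of `"control"`, `"pd"`, `"et"`.
#' @param tremor_amplitude Tremor amplitude, cm.
#' @param tremor_freq Tremor frequency, Hz (kept within the 3-10 Hz band).
#' @param tracking_lag Pursuit reaction lag, seconds.
#' @param tracking_gain Per-step pursuit gain in (0, 1].
#' @param noise_sd Isotropic positional noise SD, cm.
#' @param speed_scale Fraction of target speed the cursor can sustain;
#'   values < 1 model slowed movement via a per-step displacement cap.
#' @param force_mean Mean stylus force, device units.
#' @param force_var Stylus-force variance, device units squared.
#' @param severity Dimensionless scalar >= 0 jointly scaling the
#'   pathological components.
#' @return A list of class `"subject_profile"`.
#' @examples
#' subject_profile("pd")
#' subject_profile("pd", severity = 0.5)
#' @export
subject_profile <- function(label = c("control", "pd", "et"),
                            tremor_amplitude = NULL,
                            tremor_freq = NULL,
                            tracking_lag = NULL,
                            tracking_gain = NULL,
                            noise_sd = NULL,
                            speed_scale = NULL,
                            force_mean = 1.0,
                            force_var = NULL,
                            severity = 1.0) {
  label <- match.arg(label)
  base <- switch(label,
    control = list(tremor_amplitude = 0, tremor_freq = 5, tracking_lag = 0,
                   tracking_gain = 1, noise_sd = 0.02, speed_scale = 1,
                   force_var = 0.01),
    pd = list(tremor_amplitude = 0.1, tremor_freq = 5, tracking_lag = 0.12,
              tracking_gain = 0.85, noise_sd = 0.08, speed_scale = 0.8,
              force_var = 0.04),
    et = list(tremor_amplitude = 0.35, tremor_freq = 6, tracking_lag = 0,
              tracking_gain = 1, noise_sd = 0.02, speed_scale = 1,
              force_var = 0.01)
  )
  p <- list(
    label = label,
    tremor_amplitude = tremor_amplitude %||% base$tremor_amplitude,
    tremor_freq = tremor_freq %||% base$tremor_freq,
    tracking_lag = tracking_lag %||% base$tracking_lag,
    tracking_gain = tracking_gain %||% base$tracking_gain,
    noise_sd = noise_sd %||% base$noise_sd,
    speed_scale = speed_scale %||% base$speed_scale,
    force_mean = force_mean,
    force_var = force_var %||% base$force_var,
    severity = severity
  )
  stopifnot(
    p$tremor_amplitude >= 0, p$tremor_freq >= 3, p$tremor_freq <= 10,
    p$tracking_lag >= 0, p$tracking_gain > 0, p$tracking_gain <= 1,
    p$noise_sd >= 0, p$speed_scale > 0, p$speed_scale <= 1,
    p$force_var >= 0, p$severity >= 0
  )
  structure(p, class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s (severity %g)\n", x$label, x$severity))
  cat(sprintf("  tremor %.3g cm @ %g Hz | lag %.3g s | gain %.3g | noise %.3g cm\n",
              x$tremor_amplitude, x$tremor_freq, x$tracking_lag,
              x$tracking_gain, x$noise_sd))
  cat(sprintf("  speed_scale %.3g | force %.3g +/- var %.3g\n",
              x$speed_scale, x$force_mean, x$force_var))
  invisible(x)
}

# Control-baseline constants shared by severity interpolation.
.control_baseline <- list(noise_sd = 0.02, force_var = 0.01)

# Interpolate a profile's pathological components between the control
# baseline (severity 0) and the nominal profile (severity 1); extrapolate
# beyond. Applied once, at simulation time.
apply_severity <- function(profile) {
  s <- profile$severity
  b <- .control_baseline
  eff <- profile
  eff$tremor_amplitude <- profile$tremor_amplitude * s
  eff$tracking_lag <- profile$tracking_lag * s
  eff$tracking_gain <- max(1 - (1 - profile$tracking_gain) * s, 0.05)
  eff$noise_sd <- max(b$noise_sd + (profile$noise_sd - b$noise_sd) * s, 0)
  eff$speed_scale <- min(max(1 - (1 - profile$speed_scale) * s, 0.05), 1)
  eff$force_var <- max(b$force_var + (profile$force_var - b$force_var) * s, 0)
  eff
}

#' Simulate one trial of cursor tracking
#'
#' Drives a first-order pursuit controller along a target trace: at each
#' 10 ms step the cursor moves toward the (lagged) target position with gain
#' `tracking_gain`; when `speed_scale < 1` the per-step displacement is
#' capped at `speed_scale` times the target's per-step travel, modelling
#' slowed movement. On top of the pursuit state the simulator adds a
#' sinusoidal tremor `A sin(2 pi f t + phi)` along a random fixed direction
#' (phase and direction drawn once per trial) and isotropic Gaussian noise.
#' Stylus force is `force_mean` plus Gaussian fluctuation.
#'
#' With an all-zero pathological profile (no tremor, no lag, unit gain, zero
#' noise, `speed_scale = 1`) the cursor reproduces the target exactly.
#'
#' @param target A tibble with columns `t`, `x`, `y` (one trial's target
#'   trace, e.g. from [sample_constant_speed()]).
#' @param profile A [subject_profile()]; its `severity` is applied first.
#' @param sampling_rate Hz.
#' @param target_speed Target speed, cm/s (sets the displacement cap).
#' @param tremor_model `"sinusoid"` (default; analytic amplitude, used by the
#'   envelope-recovery checks) or `"bandnoise"` (3-10 Hz band-limited
#'   Gaussian tremor scaled to the same RMS amplitude).
#' @return A tibble with columns `t`, `target_x`, `target_y`, `cursor_x`,
#'   `cursor_y`, `force`.
#' @examples
#' tr <- sample_constant_speed(generate_path(seed = 1), duration = 3)
#' sim <- simulate_cursor(tr, subject_profile("et"))
#' head(sim)
#' @export
simulate_cursor <- function(target, profile, sampling_rate = 100,
                            target_speed = 4.25,
                            tremor_model = c("sinusoid", "bandnoise")) {
  tremor_model <- match.arg(tremor_model)
  if (nrow(target) == 0) abort("Empty target trace.")
  eff <- apply_severity(profile)
  n <- nrow(target)
  dt <- 1 / sampling_rate
  tx <- target$x; ty <- target$y

  lag_steps <- round(eff$tracking_lag * sampling_rate)
  idx <- pmax(seq_len(n) - lag_steps, 1)
  dx_des <- tx[idx]; dy_des <- ty[idx]

  cx <- numeric(n); cy <- numeric(n)
  cx[1] <- tx[1]; cy[1] <- ty[1]
  g <- eff$tracking_gain
  cap <- if (eff$speed_scale < 1) eff$speed_scale * target_speed * dt else Inf
  for (k in 2:n) {
    sx <- g * (dx_des[k] - cx[k - 1])
    sy <- g * (dy_des[k] - cy[k - 1])
    len <- sqrt(sx^2 + sy^2)
    if (len > cap) {
      sx <- sx * cap / len
      sy <- sy * cap / len
    }
    cx[k] <- cx[k - 1] + sx
    cy[k] <- cy[k - 1] + sy
  }

  if (eff$tremor_amplitude > 0) {
    psi <- runif(1, 0, 2 * pi)
    if (tremor_model == "sinusoid") {
      phi <- runif(1, 0, 2 * pi)
      osc <- eff$tremor_amplitude * sin(2 * pi * eff$tremor_freq * target$t + phi)
    } else {
      white <- rnorm(n)
      bf <- signal::butter(2, c(3, 10) / (sampling_rate / 2), type = "pass")
      band <- signal::filtfilt(bf, white)
      # scale band-limited noise to the RMS of a sinusoid of the same amplitude
      osc <- band / stats::sd(band) * eff$tremor_amplitude / sqrt(2)
    }
    cx <- cx + cos(psi) * osc
    cy <- cy + sin(psi) * osc
  }
  if (eff$noise_sd > 0) {
    cx <- cx + rnorm(n, 0, eff$noise_sd)
    cy <- cy + rnorm(n, 0, eff$noise_sd)
  }
  force <- eff$force_mean + rnorm(n, 0, sqrt(eff$force_var))

  tibble::tibble(
    t = target$t,
    target_x = tx, target_y = ty,
    cursor_x = cx, cursor_y = cy,
    force = force
  )
}

#' Simulate a full tracking session for one subject
#'
#' Generates a fresh stochastic target path per trial and simulates the
#' subject tracking it with [simulate_cursor()].
#'
#' @param profile A [subject_profile()].
#' @param cfg A [path_config()] defining trials, speed, and sampling.
#' @param subject_id Subject identifier recorded in the output.
#' @param seed Optional integer master seed.
#' @inheritParams simulate_cursor
#' @return A tibble with columns `subject_id`, `group`, `trial`, `t`,
#'   `target_x`, `target_y`, `cursor_x`, `cursor_y`, `force`; attributes
#'   `sampling_rate`, `seed`, `profile`.
#' @examples
#' s <- simulate_session(subject_profile("control"),
#'                       path_config(n_trials = 1, trial_duration = 4),
#'                       subject_id = "c01", seed = 1)
#' head(s)
#' @export
simulate_session <- function(profile, cfg = path_config(), subject_id = "s01",
                             seed = NULL,
                             tremor_model = c("sinusoid", "bandnoise")) {
  tremor_model <- match.arg(tremor_model)
  run <- function() {
    purrr::map_dfr(seq_len(cfg$n_trials), function(i) {
      path <- generate_path(cfg)
      tr <- sample_constant_speed(path, cfg, duration = cfg$trial_duration)
      sim <- simulate_cursor(tr, profile, sampling_rate = cfg$sampling_rate,
                             target_speed = cfg$speed,
                             tremor_model = tremor_model)
      dplyr::bind_cols(tibble::tibble(trial = i), sim)
    })
  }
  out <- with_seed(seed, run())
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, group = profile$label,
                   .rows = nrow(out)),
    out
  )
  attr(out, "sampling_rate") <- cfg$sampling_rate
  attr(out, "seed") <- seed
  attr(out, "profile") <- profile
  out
}

#' Simulate a cohort of tracking sessions
#'
#' Simulates `n` subjects per group, each with an independent target path
#' session and (optionally) an independently drawn profile. Group sizes
#' default to the study design this package emulates: 20 controls, 26
#' parkinsonian, 12 essential-tremor subjects.
#'
#' @param n_control,n_pd,n_et Subjects per group.
#' @param cfg A [path_config()].
#' @param profiles Named list of [subject_profile()]s (or functions returning
#'   one, called per subject for heterogeneous cohorts) for groups
#'   `control`, `pd`, `et`.
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @inheritParams simulate_cursor
#' @return A tibble: all sessions row-bound, with `subject_id` and `group`
#'   columns; attribute `profiles` holds the per-subject profiles.
#' @examples
#' coh <- simulate_cohort(2, 2, 1, path_config(n_trials = 1, trial_duration = 4),
#'                        seed = 1)
#' dplyr::count(coh, group, subject_id)
#' @export
simulate_cohort <- function(n_control = 20, n_pd = 26, n_et = 12,
                            cfg = path_config(),
                            profiles = list(control = subject_profile("control"),
                                            pd = subject_profile("pd"),
                                            et = subject_profile("et")),
                            seed = NULL,
                            tremor_model = c("sinusoid", "bandnoise")) {
  tremor_model <- match.arg(tremor_model)
  counts <- c(control = n_control, pd = n_pd, et = n_et)
  counts <- counts[counts > 0]
  if (length(counts) == 0) abort("Requested an empty cohort.")
  total <- sum(counts)
  seeds <- if (is.null(seed)) rep(list(NULL), total) else
    as.list(derive_seeds(seed, total))

  plan <- purrr::map_dfr(names(counts), function(gr) {
    tibble::tibble(group = gr, k = seq_len(counts[[gr]]))
  })
  plan$subject_id <- sprintf("%s%02d", substr(plan$group, 1, 2), plan$k)

  used_profiles <- list()
  out <- purrr::map_dfr(seq_len(total), function(i) {
    gr <- plan$group[i]
    prof <- profiles[[gr]]
    if (is.function(prof)) prof <- with_seed(seeds[[i]], prof())
    used_profiles[[plan$subject_id[i]]] <<- prof
    simulate_session(prof, cfg, subject_id = plan$subject_id[i],
                     seed = seeds[[i]], tremor_model = tremor_model)
  })
  attr(out, "sampling_rate") <- cfg$sampling_rate
  attr(out, "seed") <- seed
  attr(out, "profiles") <- used_profiles
  out
}
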