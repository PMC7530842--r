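#' Names of the eight tracking metrics
#'
#' Column names, in canonical order, of the per-epoch metric table produced
#' by [compute_metrics()].
#'
#' @return Character vector of length 8.
#' @export
metric_names <- function() {
  c("distance", "tremor", "vector_error", "tracking_angle",
    "slowness", "speed_difference", "excursion_difference", "pressure")
}

#' Filter specification for metric computation
#'
#' The non-tremor metrics are computed on a low-pass filtered cursor trace
#' (so tremor cannot confound them); the tremor metric is computed on a
#' band-pass filtered trace isolating the 3-10 Hz tremor band. Both filters
#' are zero-phase Butterworth (applied forward and backward), designed per
#' trial.
#'
#' @param lowpass_cutoff Low-pass cutoff, Hz.
#' @param tremor_band Length-2 numeric, Hz.
#' @param order Butterworth order (before the forward-backward pass).
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(lowpass_cutoff = 3, tremor_band = c(3, 10), order = 4) {
  stopifnot(lowpass_cutoff > 0, length(tremor_band) == 2,
            tremor_band[1] > 0, diff(tremor_band) > 0, order >= 1)
  structure(list(lowpass_cutoff = lowpass_cutoff, tremor_band = tremor_band,
                 order = as.integer(order)),
            class = "filter_spec")
}

zero_phase_filter <- function(x, type, cutoff, fs, order = 4) {
  ny <- fs / 2
  if (any(cutoff >= ny)) {
    abort(sprintf("Filter cutoff (%s Hz) infeasible at sampling rate %g Hz.",
                  paste(cutoff, collapse = "-"), fs))
  }
  bf <- signal::butter(order, cutoff / ny, type = type)
  # odd-reflection padding: suppresses the edge transients filtfilt would
  # otherwise ring off a trace with a large offset or trend
  n <- length(x)
  p <- min(n - 1, 3L * as.integer(fs))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(p + 1):(p + n)]
}

#' Analytic-signal amplitude envelope
#'
#' Computes the magnitude of the analytic signal (the Hilbert envelope) of a
#' real series via the frequency-domain construction: negative frequencies
#' are zeroed, positive frequencies doubled. For a pure sinusoid the
#' envelope equals its amplitude.
#'
#' @param x Numeric vector.
#' @return Numeric vector, `abs()` of the analytic signal.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' env <- analytic_envelope(sin(2 * pi * 6 * t))
#' mean(env[20:80]) # ~1
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Assign 1-second non-overlapping epochs
#'
#' Adds an `epoch` column to a session tibble: within each trial (and
#' subject, if present), consecutive blocks of `sampling_rate` samples are
#' numbered 1, 2, ...; samples in a trailing partial second get `NA` and are
#' discarded by the metric computations. Epochs never span trial boundaries.
#'
#' @param data Session tibble with columns `trial` and `t` (plus optionally
#'   `subject_id`).
#' @param sampling_rate Hz; defaults to the tibble's `sampling_rate`
#'   attribute, else inferred from `t`.
#' @return `data` with an integer `epoch` column.
#' @examples
#' s <- simulate_session(subject_profile("control"),
#'                       path_config(n_trials = 1, trial_duration = 3), seed = 1)
#' table(epoch_split(s)$epoch, useNA = "ifany")
#' @export
epoch_split <- function(data, sampling_rate = NULL) {
  fs <- sampling_rate %||% attr(data, "sampling_rate") %||% infer_fs(data$t)
  keys <- intersect(c("subject_id", "trial"), names(data))
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::mutate(grouped,
    epoch = {
      n <- dplyr::n()
      if (n < fs) warn(sprintf("Trial shorter than 1 s (%d samples): zero epochs.", n))
      e <- (seq_len(n) - 1L) %/% as.integer(fs) + 1L
      e[e > n %/% as.integer(fs)] <- NA_integer_
      e
    }
  )
  dplyr::ungroup(out)
}

infer_fs <- function(t) {
  dt <- stats::median(diff(t))
  if (!is.finite(dt) || dt <= 0) abort("Cannot infer sampling rate from `t`.")
  round(1 / dt)
}

# Per-trial metric series: returns per-sample and per-bin pieces already
# aggregated to epoch level. `trial_df` has cursor/target columns for one trial.
trial_metrics <- function(trial_df, fs, filt, b, speed_unit_factor,
                          excursion_mode) {
  n <- nrow(trial_df)
  n_epochs <- n %/% fs
  if (n_epochs == 0) return(NULL)
  used <- n_epochs * fs
  epoch_of <- rep(seq_len(n_epochs), each = fs)

  cx <- trial_df$cursor_x; cy <- trial_df$cursor_y
  tx <- trial_df$target_x; ty <- trial_df$target_y

  # low-pass cursor for all non-tremor metrics
  lx <- zero_phase_filter(cx, "low", filt$lowpass_cutoff, fs, filt$order)
  ly <- zero_phase_filter(cy, "low", filt$lowpass_cutoff, fs, filt$order)
  # band-pass cursor for the tremor envelope
  bx <- zero_phase_filter(cx, "pass", filt$tremor_band, fs, filt$order)
  by <- zero_phase_filter(cy, "pass", filt$tremor_band, fs, filt$order)

  ep_mean <- function(x) as.numeric(tapply(x[seq_len(used)], epoch_of, mean))

  # per-sample series
  dist_s <- sqrt((lx - tx)^2 + (ly - ty)^2)
  trem_s <- sqrt(analytic_envelope(bx)^2 + analytic_envelope(by)^2)
  exc_s <- if (excursion_mode == "position") sqrt(lx^2 + ly^2) else NULL

  # per-bin series (successive-sample displacement vectors of the filtered
  # traces); bin i sits between samples i and i+1 and is assigned to the
  # epoch of sample i+1
  dt <- 1 / fs
  Cx <- diff(lx); Cy <- diff(ly)
  Tx <- diff(tx); Ty <- diff(ty)
  Cn <- sqrt(Cx^2 + Cy^2); Tn <- sqrt(Tx^2 + Ty^2)

  ve <- sqrt((Cx - Tx)^2 + (Cy - Ty)^2)
  cosang <- (Cx * Tx + Cy * Ty) / (Cn * Tn)
  ang <- acos(pmin(pmax(cosang, -1), 1))
  ang[Cn == 0 | Tn == 0] <- 0 # no angular disagreement attributable
  slow <- exp(b * (Cn / dt) * speed_unit_factor)
  spd <- Cn / dt - Tn / dt
  exc_d <- Cn

  bin_epoch <- epoch_of[-1][seq_len(used - 1)]
  bin_mean <- function(x) as.numeric(tapply(x[seq_len(used - 1)], bin_epoch, mean))

  force <- trial_df$force
  pressure <- if (all(is.na(force))) rep(NA_real_, n_epochs) else
    as.numeric(tapply(force[seq_len(used)], epoch_of,
                      function(f) mean((f - mean(f))^2)))

  tibble::tibble(
    epoch = seq_len(n_epochs),
    distance = ep_mean(dist_s),
    tremor = ep_mean(trem_s),
    vector_error = bin_mean(ve),
    tracking_angle = bin_mean(ang),
    slowness = bin_mean(slow),
    speed_difference = bin_mean(spd),
    excursion_difference = if (excursion_mode == "position") ep_mean(exc_s)
                           else bin_mean(exc_d),
    pressure = pressure
  )
}

#' Compute the eight tracking metrics per 1-second epoch
#'
#' Transforms a session of paired target/cursor/force samples into one
#' 8-dimensional metric vector per 1-second non-overlapping epoch:
#'
#' * `distance` — mean Euclidean distance between (low-pass) cursor and
#'   target positions, cm.
#' * `tremor` — mean root-sum-square of the per-coordinate analytic-signal
#'   envelopes of the 3-10 Hz band-passed cursor, cm.
#' * `vector_error` — mean magnitude of the difference between cursor and
#'   target per-bin displacement vectors, cm.
#' * `tracking_angle` — mean angle between cursor and target displacement
#'   vectors, radians in `[0, pi]` (0 when either vector vanishes).
#' * `slowness` — mean of `exp(b * speed)` with cursor speed in mm/s and
#'   `b = -0.042`; 1 at rest, decreasing with speed (a bradykinesia proxy).
#' * `speed_difference` — mean cursor-minus-target speed, cm/s.
#' * `excursion_difference` — mean distance of the (low-pass) cursor
#'   position from the screen origin, cm (`excursion_mode = "position"`), or
#'   the mean bin-displacement magnitude (`"displacement"`).
#' * `pressure` — population variance of the stylus force within the epoch.
#'
#' All metrics except `tremor` use the low-pass filtered cursor so that
#' tremor cannot confound them. Displacement bins are successive-sample
#' differences of the filtered traces. Trailing partial seconds are dropped;
#' filtering never crosses trial boundaries.
#'
#' @param data Session tibble (one or many subjects) with columns `trial`,
#'   `t`, `target_x`, `target_y`, `cursor_x`, `cursor_y` and optionally
#'   `force`, `subject_id`, `group`.
#' @param filt A [filter_spec()].
#' @param sampling_rate Hz; defaults to the `sampling_rate` attribute.
#' @param b Slowness exponent per (mm/s); the transform's curvature sits in
#'   the responsive range at typical task speeds.
#' @param speed_unit Unit of the speed fed to the slowness exponential:
#'   `"mm"` (default) or `"cm"` per second. `b` is interpreted in this unit.
#' @param excursion_mode `"position"` (default) or `"displacement"`.
#' @return A tibble with one row per epoch: identifier columns plus the
#'   eight metric columns of [metric_names()].
#' @examples
#' s <- simulate_session(subject_profile("pd"),
#'                       path_config(n_trials = 1, trial_duration = 5), seed = 1)
#' compute_metrics(s)
#' @export
compute_metrics <- function(data, filt = filter_spec(), sampling_rate = NULL,
                            b = -0.042, speed_unit = c("mm", "cm"),
                            excursion_mode = c("position", "displacement")) {
  speed_unit <- match.arg(speed_unit)
  excursion_mode <- match.arg(excursion_mode)
  fs <- sampling_rate %||% attr(data, "sampling_rate") %||% infer_fs(data$t)
  need <- c("trial", "t", "target_x", "target_y", "cursor_x", "cursor_y")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"force" %in% names(data)) data$force <- NA_real_
  unit_factor <- if (speed_unit == "mm") 10 else 1

  keys <- intersect(c("subject_id", "group", "trial"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      res <- trial_metrics(df, fs, filt, b, unit_factor, excursion_mode)
      if (is.null(res)) {
        warn("Trial shorter than 1 s: no epochs computed.")
        res <- tibble::tibble(epoch = integer(0))
      }
      res
    }) |>
    dplyr::ungroup()
}

#' Pairwise metric correlation matrix
#'
#' For each subject, metric epoch values are first normalized (z-scored)
#' against the pooled control-subject distribution of that metric, then
#' averaged per subject. Pearson r-squared is computed between every metric
#' pair across the subjects of each requested group — a redundancy screen
#' across the metric panel.
#'
#' @param metrics A metric table from [compute_metrics()] with `subject_id`
#'   and `group` columns.
#' @param groups Groups to correlate within (default: all present).
#' @param control_label Group label providing the normalization reference.
#' @return A tibble with columns `group`, `metric_a`, `metric_b`, `r2`.
#'   Zero-variance metrics yield `NA` entries with a warning.
#' @export
metric_correlation <- function(metrics, groups = NULL, control_label = "control") {
  stopifnot(all(c("subject_id", "group") %in% names(metrics)))
  mcols <- intersect(metric_names(), names(metrics))
  ctrl <- dplyr::filter(metrics, .data$group == control_label)
  if (nrow(ctrl) == 0) abort("No control rows to normalize against.")
  centre <- purrr::map_dbl(mcols, ~ mean(ctrl[[.x]], na.rm = TRUE))
  scale_ <- purrr::map_dbl(mcols, ~ stats::sd(ctrl[[.x]], na.rm = TRUE))
  names(centre) <- names(scale_) <- mcols
  if (any(scale_ == 0 | is.na(scale_))) {
    warn("Zero-variance metric in the control pool: correlations set to NA.")
  }

  per_subject <- metrics |>
    dplyr::mutate(dplyr::across(dplyr::all_of(mcols),
                                ~ (.x - centre[dplyr::cur_column()]) /
                                  scale_[dplyr::cur_column()])) |>
    dplyr::group_by(.data$group, .data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(mcols), ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")

  groups <- groups %||% unique(per_subject$group)
  purrr::map_dfr(groups, function(gr) {
    sub <- dplyr::filter(per_subject, .data$group == gr)
    if (nrow(sub) < 3) abort(sprintf("Need >= 3 subjects in group '%s'.", gr))
    grid <- tidyr::expand_grid(metric_a = mcols, metric_b = mcols)
    grid$r2 <- purrr::map2_dbl(grid$metric_a, grid$metric_b, function(a, b2) {
      xa <- sub[[a]]; xb <- sub[[b2]]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0 ||
          any(!is.finite(xa)) || any(!is.finite(xb))) return(NA_real_)
      cor(xa, xb)^2
    })
    dplyr::bind_cols(tibble::tibble(group = gr, .rows = nrow(grid)), grid)
  })
}

#' Calibrate the slowness exponent from observed speeds
#'
#' Chooses `b` so the exponential transform `exp(b * v)` has its maximum
#' curvature (in the sense of the inflection of its response) anchored at
#' the empirical 80th percentile of cursor speed: `b = -2 / v_80`, the rate
#' at which `exp(b v)` has dropped to `e^-2` at `v_80`. Offered as an
#' optional, data-driven alternative to the fixed default.
#'
#' @param speeds Numeric vector of cursor speeds (same unit `b` will be
#'   applied in, mm/s by default in [compute_metrics()]).
#' @return Scalar `b` (negative).
#' @export
calibrate_slowness_b <- function(speeds) {
  v80 <- stats::quantile(speeds, 0.8, names = FALSE)
  if (v80 <= 0) abort("80th-percentile speed is not positive.")
  -2 / v80
}
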