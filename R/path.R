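#' Configuration for the tracking-task target path
#'
#' Bundles every tunable of the stochastic target path and its sampling: the
#' number of chained cubic Bezier curves per trial, the control-point radius
#' and curvature ranges, the constant animation speed, the sampling rate, and
#' the trial layout of a session.
#'
#' Each trial's path is built from `n_segments` cubic Bezier curves chained
#' end-to-end. Control points are placed on circles centred on the previous
#' control point, with radius drawn uniformly from `radius_range` (cm) and a
#' signed turning angle drawn uniformly from `curvature_range` (degrees).
#' The target is animated along the path at `speed` cm/s and sampled at
#' `sampling_rate` Hz.
#'
#' @param n_segments Number of Bezier curves chained per trial path.
#' @param radius_range Length-2 numeric, cm; control-point radius range.
#' @param curvature_range Length-2 numeric, degrees; turning-angle range.
#' @param speed Constant target speed, cm/s.
#' @param sampling_rate Sampling frequency, Hz.
#' @param n_trials Number of trials per session.
#' @param trial_duration Nominal trial length, seconds.
#' @param target_radius Radius of the rendered target disc, cm (metadata only).
#' @param screen_width,screen_height Usable screen size, cm. The screen is the
#'   rectangle `[0, screen_width] x [0, screen_height]`.
#' @param bound_margin Distance from a screen edge, cm, inside which the turn
#'   direction is forced away from that edge.
#' @param max_retries Rejection-sampling budget per segment.
#'
#' @return A list of class `"path_config"`.
#' @examples
#' cfg <- path_config(n_trials = 1, trial_duration = 5)
#' cfg$speed
#' @export
path_config <- function(n_segments = 20,
                        radius_range = c(2.0, 2.4),
                        curvature_range = c(60, 75),
                        speed = 4.25,
                        sampling_rate = 100,
                        n_trials = 15,
                        trial_duration = 25,
                        target_radius = 0.4,
                        screen_width = 19.7,
                        screen_height = 14.7,
                        bound_margin = 2.5,
                        max_retries = 100) {
  stopifnot(
    length(radius_range) == 2, diff(radius_range) >= 0, radius_range[1] > 0,
    length(curvature_range) == 2, diff(curvature_range) >= 0,
    speed > 0, sampling_rate > 0, n_segments >= 1, n_trials >= 1,
    trial_duration > 0, screen_width > 0, screen_height > 0
  )
  if (2 * bound_margin >= min(screen_width, screen_height)) {
    abort("`bound_margin` leaves no interior: margins overlap.")
  }
  structure(
    list(
      n_segments = as.integer(n_segments),
      radius_range = as.numeric(radius_range),
      curvature_range = as.numeric(curvature_range),
      speed = speed,
      sampling_rate = sampling_rate,
      n_trials = as.integer(n_trials),
      trial_duration = trial_duration,
      target_radius = target_radius,
      screen_width = screen_width,
      screen_height = screen_height,
      bound_margin = bound_margin,
      max_retries = as.integer(max_retries)
    ),
    class = "path_config"
  )
}

#' @export
print.path_config <- function(x, ...) {
  cat("<path_config>\n")
  cat(sprintf("  %d segments/trial, radius [%.1f, %.1f] cm, curvature [%g, %g] deg\n",
              x$n_segments, x$radius_range[1], x$radius_range[2],
              x$curvature_range[1], x$curvature_range[2]))
  cat(sprintf("  speed %.2f cm/s @ %g Hz; %d trials x %g s; screen %.1f x %.1f cm\n",
              x$speed, x$sampling_rate, x$n_trials, x$trial_duration,
              x$screen_width, x$screen_height))
  invisible(x)
}

#' Evaluate a cubic Bezier curve
#'
#' Bernstein-form evaluation
#' \deqn{B(t) = (1-t)^3 P_0 + 3(1-t)^2 t\, P_1 + 3(1-t) t^2 P_2 + t^3 P_3,}
#' the curve family from which the target path is built.
#'
#' @param seg A Bezier segment: a list with planar points `P0`, `P1`, `P2`,
#'   `P3` (length-2 numerics, cm).
#' @param t Curve parameter(s) in `[0, 1]`.
#' @return A tibble with columns `t`, `x`, `y`.
#' @examples
#' seg <- list(P0 = c(0, 0), P1 = c(0, 1), P2 = c(1, 1), P3 = c(1, 0))
#' evaluate_bezier(seg, c(0, 0.5, 1))
#' @export
evaluate_bezier <- function(seg, t) {
  if (any(t < 0 | t > 1)) abort("Bezier parameter `t` must lie in [0, 1].")
  s <- 1 - t
  b0 <- s^3; b1 <- 3 * s^2 * t; b2 <- 3 * s * t^2; b3 <- t^3
  tibble::tibble(
    t = t,
    x = b0 * seg$P0[1] + b1 * seg$P1[1] + b2 * seg$P2[1] + b3 * seg$P3[1],
    y = b0 * seg$P0[2] + b1 * seg$P1[2] + b2 * seg$P2[2] + b3 * seg$P3[2]
  )
}

rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

in_bounds <- function(p, cfg) {
  p[1] >= 0 && p[1] <= cfg$screen_width && p[2] >= 0 && p[2] <= cfg$screen_height
}

near_bound <- function(p, cfg) {
  m <- cfg$bound_margin
  p[1] < m || p[2] < m || p[1] > cfg$screen_width - m || p[2] > cfg$screen_height - m
}

# A pose (point, unit heading) is recoverable if a maximal-turn next segment
# (radii at the top of the range, curvature at the top of the range) fits in
# the screen for at least one turn direction. Used as a one-segment lookahead
# so chained generation never wedges itself against an edge or corner.
pose_recoverable <- function(p, d, cfg) {
  rmax <- cfg$radius_range[2]
  th <- cfg$curvature_range[2] * pi / 180
  for (s in c(1, -1)) {
    q1 <- p + rmax * d
    d1 <- rot2(d, s * th)
    q2 <- q1 + rmax * d1
    q3 <- q2 + rmax * rot2(d1, s * th)
    if (in_bounds(q1, cfg) && in_bounds(q2, cfg) && in_bounds(q3, cfg)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Generate one Bezier segment of the target path
#'
#' Places `P1` collinear with the incoming direction (so chained segments join
#' without kinks), then walks `P2` and `P3` around circles centred on the
#' previous control point: radius drawn from `cfg$radius_range`, turning angle
#' from `cfg$curvature_range`, signed by the turn direction. The turn
#' direction is random unless `start` lies within `cfg$bound_margin` of a
#' screen edge, in which case the path is forced to curve toward the screen
#' interior. Candidate segments whose control points leave the screen — or
#' whose exit heading could push the next segment's first control point off
#' screen — are rejected and redrawn, up to `cfg$max_retries` times.
#'
#' @param start Segment start point `P0` (cm), strictly inside the screen.
#' @param dir_in Unit vector: incoming direction (previous segment's
#'   `P3 - P2` direction, or a random heading for the first segment).
#' @param cfg A [path_config()].
#' @return A list with points `P0`..`P3` and the signed `turn` used.
#' @keywords internal
generate_segment <- function(start, dir_in, cfg) {
  if (!in_bounds(start, cfg)) abort("Segment start point lies outside the screen bounds.")
  centre <- c(cfg$screen_width, cfg$screen_height) / 2
  forced <- near_bound(start, cfg)
  rmax <- cfg$radius_range[2]
  theta_mid <- mean(cfg$curvature_range) * pi / 180

  for (attempt in seq_len(cfg$max_retries)) {
    if (forced) {
      # pick the sign whose mid-range rotation points most toward the interior;
      # if that sign keeps failing, fall back to the other (still bounded by
      # the in-screen acceptance test below)
      to_centre <- centre - start
      turn <- if (sum(rot2(dir_in, theta_mid) * to_centre) >=
                  sum(rot2(dir_in, -theta_mid) * to_centre)) 1 else -1
      if (attempt > cfg$max_retries %/% 2) turn <- -turn
    } else {
      turn <- sample(c(-1, 1), 1)
    }
    r <- runif(3, cfg$radius_range[1], cfg$radius_range[2])
    th <- runif(2, cfg$curvature_range[1], cfg$curvature_range[2]) * pi / 180 * turn

    P0 <- start
    P1 <- P0 + r[1] * dir_in
    d1 <- rot2(dir_in, th[1])
    P2 <- P1 + r[2] * d1
    d2 <- rot2(d1, th[2]) # angle steps accumulate along the running direction
    P3 <- P2 + r[3] * d2

    dir_out <- (P3 - P2) / sqrt(sum((P3 - P2)^2))
    ok <- in_bounds(P1, cfg) && in_bounds(P2, cfg) && in_bounds(P3, cfg) &&
      pose_recoverable(P3, dir_out, cfg)
    if (ok) {
      return(list(P0 = P0, P1 = P1, P2 = P2, P3 = P3, turn = turn))
    }
  }
  abort(sprintf(
    "Could not place a segment satisfying the screen-bound constraint after %d retries (start = [%.2f, %.2f]).",
    cfg$max_retries, start[1], start[2]
  ))
}

#' Generate a stochastic target path
#'
#' Chains `cfg$n_segments` cubic Bezier curves into one continuous path:
#' each segment starts exactly where the previous one ended (C0 continuity)
#' and its first control point continues the previous exit direction (G1
#' continuity, preventing kinks). The path starts at the screen centre with a
#' random initial heading.
#'
#' @param cfg A [path_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `"target_path"` with elements `segments` (list of
#'   `P0`..`P3` control-point lists), `cfg`, and `seed`.
#' @examples
#' path <- generate_path(path_config(), seed = 1)
#' length(path$segments)
#' @export
generate_path <- function(cfg = path_config(), seed = NULL) {
  with_seed(seed, {
    last_err <- NULL
    # a wedged chain (no legal continuation despite the lookahead) is rare;
    # restart the whole path with a fresh heading rather than giving up
    for (path_attempt in 1:20) {
      res <- tryCatch({
        start <- c(cfg$screen_width, cfg$screen_height) / 2
        phi <- runif(1, 0, 2 * pi)
        dir_in <- c(cos(phi), sin(phi))
        segments <- vector("list", cfg$n_segments)
        for (k in seq_len(cfg$n_segments)) {
          seg <- generate_segment(start, dir_in, cfg)
          segments[[k]] <- seg
          start <- seg$P3
          dir_in <- (seg$P3 - seg$P2) / sqrt(sum((seg$P3 - seg$P2)^2))
        }
        structure(list(segments = segments, cfg = cfg, seed = seed),
                  class = "target_path")
      }, error = function(e) e)
      if (!inherits(res, "error")) return(res)
      last_err <- res
    }
    abort("Path generation failed after 20 full restarts.", parent = last_err)
  })
}

#' @export
print.target_path <- function(x, ...) {
  cat(sprintf("<target_path> %d segments on a %.1f x %.1f cm screen\n",
              length(x$segments), x$cfg$screen_width, x$cfg$screen_height))
  invisible(x)
}

#' @rdname generate_path
#' @param x A `target_path`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per control point (`segment`,
#'   `point`, `x`, `y`).
#' @export
tidy.target_path <- function(x, ...) {
  purrr::imap_dfr(x$segments, function(seg, k) {
    tibble::tibble(
      segment = k,
      point = c("P0", "P1", "P2", "P3"),
      x = c(seg$P0[1], seg$P1[1], seg$P2[1], seg$P3[1]),
      y = c(seg$P0[2], seg$P1[2], seg$P2[2], seg$P3[2])
    )
  })
}

# Dense piecewise-linear approximation of the path: n_dense points per
# segment, with cumulative chord length. Used for arc-length reparameterization.
dense_path_points <- function(path, n_dense = 1000) {
  pts <- purrr::map_dfr(path$segments, function(seg) {
    evaluate_bezier(seg, seq(0, 1, length.out = n_dense))[, c("x", "y")]
  })
  dx <- diff(pts$x); dy <- diff(pts$y)
  pts$arc <- c(0, cumsum(sqrt(dx^2 + dy^2)))
  pts
}

#' Sample a target path at constant speed
#'
#' Reparameterizes the path by arc length (cumulative chord length on a dense
#' evaluation grid, 1000 points per segment, with linear interpolation) and
#' samples it so the target advances `cfg$speed / cfg$sampling_rate` cm
#' between successive samples — a target moving at constant speed.
#'
#' @param path A [generate_path()] result.
#' @param cfg A [path_config()]; defaults to the config stored in `path`.
#' @param duration Optional cap, seconds; the trace is truncated to this
#'   length if the path is longer.
#' @return A tibble with columns `t` (s), `x`, `y` (cm).
#' @examples
#' tr <- sample_constant_speed(generate_path(seed = 1))
#' head(tr)
#' @export
sample_constant_speed <- function(path, cfg = path$cfg, duration = NULL) {
  dense <- dense_path_points(path)
  total <- dense$arc[nrow(dense)]
  step <- cfg$speed / cfg$sampling_rate
  if (total < step) abort("Path is shorter than one sample interval.")
  n_samp <- floor(total / step + 1e-9) + 1
  if (!is.null(duration)) n_samp <- min(n_samp, round(duration * cfg$sampling_rate))
  s <- (seq_len(n_samp) - 1) * step
  tibble::tibble(
    t = (seq_len(n_samp) - 1) / cfg$sampling_rate,
    x = approx(dense$arc, dense$x, xout = s, ties = "ordered")$y,
    y = approx(dense$arc, dense$y, xout = s, ties = "ordered")$y
  )
}

#' Generate the target trace for a whole session
#'
#' Generates one independent path per trial and samples each at constant
#' speed, truncated to `cfg$trial_duration` seconds. Trials are concatenated
#' into a single tibble with a `trial` column; each trial's clock restarts at
#' zero.
#'
#' @param cfg A [path_config()].
#' @param seed Optional integer master seed; per-trial seeds are derived
#'   from it.
#' @return A tibble with columns `trial`, `t`, `target_x`, `target_y`, and
#'   attributes `sampling_rate`, `speed`, `seed`.
#' @examples
#' tr <- target_trace(path_config(n_trials = 2, trial_duration = 5), seed = 1)
#' dplyr::count(tr, trial)
#' @export
target_trace <- function(cfg = path_config(), seed = NULL) {
  trial_seeds <- if (is.null(seed)) rep(list(NULL), cfg$n_trials) else
    as.list(derive_seeds(seed, cfg$n_trials))
  out <- purrr::map_dfr(seq_len(cfg$n_trials), function(i) {
    path <- generate_path(cfg, seed = trial_seeds[[i]])
    tr <- sample_constant_speed(path, cfg, duration = cfg$trial_duration)
    tibble::tibble(trial = i, t = tr$t, target_x = tr$x, target_y = tr$y)
  })
  attr(out, "sampling_rate") <- cfg$sampling_rate
  attr(out, "speed") <- cfg$speed
  attr(out, "seed") <- seed
  out
}

#' Export a target path to JSON
#'
#' Writes the control points of every segment (cm) together with the
#' generating configuration and seed, so a path can be re-rendered elsewhere.
#'
#' @param path A `target_path`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_path_json <- function(path, file) {
  doc <- list(
    format_version = "1.0",
    seed = path$seed,
    config = unclass(path$cfg),
    segments = purrr::map(path$segments, function(seg) {
      list(P0 = seg$P0, P1 = seg$P1, P2 = seg$P2, P3 = seg$P3)
    })
  )
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
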