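# de Casteljau subdivision: an independent route to a Bezier point.
de_casteljau <- function(seg, t) {
  pts <- list(seg$P0, seg$P1, seg$P2, seg$P3)
  while (length(pts) > 1) {
    pts <- purrr::map2(pts[-length(pts)], pts[-1],
                       function(a, b) (1 - t) * a + t * b)
  }
  pts[[1]]
}

random_segment <- function() {
  list(P0 = runif(2, 0, 10), P1 = runif(2, 0, 10),
       P2 = runif(2, 0, 10), P3 = runif(2, 0, 10))
}

test_that("Bernstein evaluation hits the endpoints and matches de Casteljau", {
  seg <- list(P0 = c(0, 0), P1 = c(0, 1), P2 = c(1, 1), P3 = c(1, 0))
  expect_equal(unlist(evaluate_bezier(seg, 0.5)[, c("x", "y")]),
               c(x = 0.5, y = 0.75))
  withr::with_seed(7, {
    for (i in 1:25) {
      s <- random_segment()
      expect_equal(unlist(evaluate_bezier(s, 0)[, c("x", "y")]),
                   c(x = s$P0[1], y = s$P0[2]))
      expect_equal(unlist(evaluate_bezier(s, 1)[, c("x", "y")]),
                   c(x = s$P3[1], y = s$P3[2]))
      tt <- runif(1)
      expect_equal(unlist(evaluate_bezier(s, tt)[, c("x", "y")]),
                   setNames(de_casteljau(s, tt), c("x", "y")),
                   tolerance = 1e-12)
    }
  })
  expect_error(evaluate_bezier(seg, 1.5), "\\[0, 1\\]")
  expect_error(evaluate_bezier(seg, -0.1), "\\[0, 1\\]")
})

test_that("generated paths have the configured segment count, exact joins, and no kinks", {
  cfg <- path_config()
  for (seed in 1:5) {
    p <- generate_path(cfg, seed = seed)
    expect_length(p$segments, 20)
    for (k in 2:length(p$segments)) {
      a <- p$segments[[k - 1]]
      b <- p$segments[[k]]
      expect_identical(a$P3, b$P0) # C0: shared point, not approximate
      d_out <- (a$P3 - a$P2) / sqrt(sum((a$P3 - a$P2)^2))
      d_in <- (b$P1 - b$P0) / sqrt(sum((b$P1 - b$P0)^2))
      # small-angle: |sin| of the angle between unit headings
      ang <- abs(d_out[1] * d_in[2] - d_out[2] * d_in[1])
      expect_lt(ang, 1e-9) # G1: collinear control points across the join
      expect_gt(sum(d_out * d_in), 0)
    }
  }
  expect_length(generate_path(path_config(n_segments = 1), seed = 3)$segments, 1)
})

test_that("control-point radii and turning angles stay in their configured ranges", {
  cfg <- path_config()
  radii <- c()
  angles <- c()
  for (seed in 1:25) {
    p <- generate_path(cfg, seed = seed)
    for (seg in p$segments) {
      radii <- c(radii, sqrt(sum((seg$P1 - seg$P0)^2)),
                 sqrt(sum((seg$P2 - seg$P1)^2)),
                 sqrt(sum((seg$P3 - seg$P2)^2)))
      v1 <- seg$P1 - seg$P0
      v2 <- seg$P2 - seg$P1
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      angles <- c(angles, ang)
    }
  }
  expect_true(all(radii >= 2.0 - 1e-12 & radii <= 2.4 + 1e-12))
  expect_true(all(angles >= 60 - 1e-9 & angles <= 75 + 1e-9))
})

test_that("paths near a screen edge curve toward the interior and stay in bounds", {
  cfg <- path_config()
  # start 1.2 cm from the right edge, heading parallel to it: the forced
  # turn must curve the segment toward the interior (smaller x), never
  # closer to the edge
  withr::with_seed(11, {
    seg <- mestrack:::generate_segment(c(18.5, 7.35), c(0, 1), cfg)
  })
  dense <- evaluate_bezier(seg, seq(0, 1, length.out = 500))
  expect_true(all(dense$x <= cfg$screen_width & dense$x >= 0))
  expect_true(all(dense$y <= cfg$screen_height & dense$y >= 0))
  expect_lte(max(dense$x), 18.5 + 1e-9)
  expect_equal(seg$turn, 1) # counterclockwise from +y heads toward -x, the interior
  # heading straight at a nearby wall is infeasible under the collinearity
  # rule (the first control point must continue >= 2 cm straight)
  expect_error(mestrack:::generate_segment(c(18.5, 7.35), c(1, 0), cfg),
               "screen-bound constraint")
  expect_error(mestrack:::generate_segment(c(-1, 5), c(1, 0), cfg), "outside")
})

test_that("all sampled path points lie inside the screen across many seeds", {
  cfg <- path_config()
  for (seed in 101:140) {
    tr <- sample_constant_speed(generate_path(cfg, seed = seed))
    expect_true(all(tr$x >= 0 & tr$x <= cfg$screen_width))
    expect_true(all(tr$y >= 0 & tr$y <= cfg$screen_height))
  }
})

test_that("a straight 4.25 cm segment samples to 101 uniform steps over 1 s", {
  cfg <- path_config()
  seg <- list(P0 = c(1, 1), P1 = c(1 + 4.25 / 3, 1),
              P2 = c(1 + 2 * 4.25 / 3, 1), P3 = c(1 + 4.25, 1))
  path <- structure(list(segments = list(seg), cfg = cfg, seed = NULL),
                    class = "target_path")
  tr <- sample_constant_speed(path, cfg)
  expect_equal(nrow(tr), 101)
  expect_equal(max(tr$t), 1.0)
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(steps, rep(0.0425, 100), tolerance = 1e-6)
})

test_that("constant-speed sampling meets the 1% speed tolerance", {
  cfg <- path_config()
  for (seed in c(2, 3, 5)) {
    tr <- sample_constant_speed(generate_path(cfg, seed = seed))
    v <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) * cfg$sampling_rate
    expect_lt(sd(v) / mean(v), 0.01)
    expect_lt(abs(mean(v) - 4.25) / 4.25, 0.01)
    expect_lt(max(abs(v - cfg$speed)) / cfg$speed, 0.01)
  }
})

test_that("trace duration matches Gauss-Legendre arc length of the segments", {
  skip_if_not_installed("pracma")
  cfg <- path_config()
  p <- generate_path(cfg, seed = 9)
  # |B'(t)| integrated with 64-node Gauss-Legendre quadrature per segment
  gl <- pracma::gaussLegendre(64, 0, 1)
  seg_len <- function(seg) {
    dBx <- function(t) {
      3 * (1 - t)^2 * (seg$P1[1] - seg$P0[1]) +
        6 * (1 - t) * t * (seg$P2[1] - seg$P1[1]) +
        3 * t^2 * (seg$P3[1] - seg$P2[1])
    }
    dBy <- function(t) {
      3 * (1 - t)^2 * (seg$P1[2] - seg$P0[2]) +
        6 * (1 - t) * t * (seg$P2[2] - seg$P1[2]) +
        3 * t^2 * (seg$P3[2] - seg$P2[2])
    }
    sum(gl$w * sqrt(dBx(gl$x)^2 + dBy(gl$x)^2))
  }
  total <- sum(purrr::map_dbl(p$segments, seg_len))
  tr <- sample_constant_speed(p, cfg)
  travelled <- (nrow(tr) - 1) * cfg$speed / cfg$sampling_rate
  expect_lt(abs(travelled - total) / total, 0.002)
})

test_that("path and trace generation are deterministic under a fixed seed", {
  cfg <- path_config(n_trials = 2, trial_duration = 5)
  p1 <- generate_path(cfg, seed = 77)
  p2 <- generate_path(cfg, seed = 77)
  expect_identical(tidy(p1), tidy(p2))
  t1 <- target_trace(cfg, seed = 77)
  t2 <- target_trace(cfg, seed = 77)
  expect_identical(t1$target_x, t2$target_x)
  expect_false(identical(target_trace(cfg, seed = 78)$target_x, t1$target_x))
})

test_that("path JSON export round-trips the control points", {
  p <- generate_path(path_config(n_segments = 3), seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_path_json(p, f)
  doc <- jsonlite::read_json(f)
  expect_length(doc$segments, 3)
  expect_equal(unlist(doc$segments[[1]]$P0), p$segments[[1]]$P0)
})
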