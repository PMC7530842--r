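make_session <- function(cursor_x, cursor_y, target_x = cursor_x,
                         target_y = cursor_y, force = 1, fs = 100) {
  n <- length(cursor_x)
  s <- tibble::tibble(
    trial = 1L, t = (seq_len(n) - 1) / fs,
    target_x = target_x, target_y = target_y,
    cursor_x = cursor_x, cursor_y = cursor_y, force = force
  )
  attr(s, "sampling_rate") <- fs
  s
}

test_that("epoch splitting floors to whole seconds and never crosses trials", {
  t1 <- tibble::tibble(trial = 1L, t = (0:2539) / 100)
  out <- epoch_split(t1, sampling_rate = 100)
  expect_equal(max(out$epoch, na.rm = TRUE), 25)
  expect_equal(sum(is.na(out$epoch)), 40)
  expect_equal(as.integer(table(out$epoch)), rep(100L, 25))

  short <- tibble::tibble(trial = 1L, t = (0:89) / 100)
  expect_warning(out2 <- epoch_split(short, sampling_rate = 100), "shorter")
  expect_true(all(is.na(out2$epoch)))

  two <- dplyr::bind_rows(
    tibble::tibble(trial = 1L, t = (0:149) / 100),
    tibble::tibble(trial = 2L, t = (0:149) / 100)
  )
  out3 <- epoch_split(two, sampling_rate = 100)
  per_trial <- dplyr::summarise(dplyr::group_by(out3, trial),
                                n_ep = dplyr::n_distinct(epoch, na.rm = TRUE))
  expect_equal(per_trial$n_ep, c(1, 1)) # epochs restart per trial
  # conservation: epoch samples + discarded tail = trial length
  expect_equal(sum(!is.na(out3$epoch)) + sum(is.na(out3$epoch)), 300)
  expect_equal(sum(!is.na(out3$epoch)), 200)
})

test_that("a full session yields trials x floor(duration) epochs", {
  s <- simulate_session(clean_profile("control"), small_cfg(3, 8), seed = 2)
  m <- compute_metrics(s)
  expect_equal(nrow(m), 3 * 8)
  expect_equal(sort(unique(m$trial)), 1:3)
})

test_that("tremor metric recovers a pure sinusoid and rejects out-of-band motion", {
  n <- 1000
  tt <- (0:(n - 1)) / 100
  base <- session_with_cursor(0, 0)
  sine6 <- session_with_cursor(0.3 * sin(2 * pi * 6 * base$t), 0)
  m6 <- compute_metrics(sine6)
  expect_lt(abs(mean(m6$tremor) - 0.3) / 0.3, 0.05)

  still <- make_session(rep(5, n), rep(3, n))
  expect_lt(mean(compute_metrics(still)$tremor), 1e-6)

  sine2 <- session_with_cursor(0.3 * sin(2 * pi * 2 * base$t), 0)
  expect_lt(mean(compute_metrics(sine2)$tremor), 0.05 * 0.3)
})

test_that("identity tracking yields (near-)zero positional metrics", {
  m <- compute_metrics(session_with_cursor(0, 0))
  expect_lt(mean(m$distance), 0.01)
  expect_lt(mean(m$vector_error), 0.01)
  expect_lt(mean(m$tracking_angle), 0.01)
  expect_lt(abs(mean(m$speed_difference)), 0.01)
  expect_lt(mean(m$tremor), 0.01)
})

test_that("slowness follows the exponential speed transform exactly", {
  n <- 500
  # stationary cursor: speed 0 -> slowness exp(0) = 1
  still <- make_session(rep(2, n), rep(2, n),
                        target_x = 2 + (0:(n - 1)) * 0.0425, target_y = rep(2, n))
  m0 <- compute_metrics(still)
  expect_equal(mean(m0$slowness), 1, tolerance = 1e-9)
  expect_equal(mean(m0$distance), mean(abs(still$target_x - 2)), tolerance = 0.05)

  # steady 1 cm/s = 10 mm/s -> exp(-0.042 * 10)
  v <- 1
  line <- make_session(2 + (0:(n - 1)) * v / 100, rep(2, n))
  m1 <- compute_metrics(line)
  expect_equal(mean(m1$slowness), exp(-0.042 * 10), tolerance = 1e-6)
  expect_equal(mean(m1$speed_difference), 0, tolerance = 1e-9)
  expect_equal(mean(m1$tracking_angle), 0, tolerance = 1e-9)

  # cm-per-second speed unit rescales the exponent
  m2 <- compute_metrics(line, speed_unit = "cm")
  expect_equal(mean(m2$slowness), exp(-0.042 * 1), tolerance = 1e-6)
})

test_that("slowness decreases strictly with speed and is 1 at rest", {
  vals <- purrr::map_dbl(c(0, 0.5, 1, 2, 4), function(v) {
    n <- 300
    s <- make_session(2 + (0:(n - 1)) * v / 100, rep(2, n))
    mean(compute_metrics(s)$slowness)
  })
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1, tolerance = 1e-9)
})

test_that("pressure is the population variance of force within each epoch", {
  n <- 300
  expect_equal(compute_metrics(make_session(rep(1, n), rep(1, n),
                                            force = 7))$pressure,
               rep(0, 3))
  alternating <- rep(c(1, -1), n / 2) + 5
  expect_equal(compute_metrics(make_session(rep(1, n), rep(1, n),
                                            force = alternating))$pressure,
               rep(1, 3), tolerance = 1e-12)
  withr::with_seed(8, {
    g <- rnorm(10000, 0, 2)
    mg <- compute_metrics(make_session(rep(1, 10000), rep(1, 10000), force = g))
    expect_lt(abs(mean(mg$pressure) - 4) / 4, 0.1)
  })
})

test_that("force-free sessions yield absent pressure but intact motion metrics", {
  s <- session_with_cursor(0, 0)
  s$force <- NULL
  m <- compute_metrics(s)
  expect_true(all(is.na(m$pressure)))
  expect_true(all(is.finite(m$distance)))
})

test_that("metrics respect the expected geometric invariances", {
  base <- session_with_cursor(0.2 * sin(2 * pi * 1.1 * base_target()$t),
                              0.1 * cos(2 * pi * 0.7 * base_target()$t))
  m0 <- compute_metrics(base)

  shifted <- dplyr::mutate(base, cursor_x = cursor_x + 3, target_x = target_x + 3,
                           cursor_y = cursor_y - 2, target_y = target_y - 2)
  attr(shifted, "sampling_rate") <- 100
  m1 <- compute_metrics(shifted)
  for (col in c("distance", "vector_error", "tremor", "tracking_angle",
                "slowness", "speed_difference")) {
    expect_lt(max(abs(m1[[col]] - m0[[col]])), 1e-6, label = col)
  }
  # excursion is origin-referenced by design: translation changes it
  expect_false(isTRUE(all.equal(m1$excursion_difference,
                                m0$excursion_difference, tolerance = 1e-4)))

  th <- 0.7
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                             y = sin(th) * x + cos(th) * y)
  rc <- rot(base$cursor_x, base$cursor_y)
  rt <- rot(base$target_x, base$target_y)
  rotated <- dplyr::mutate(base, cursor_x = rc$x, cursor_y = rc$y,
                           target_x = rt$x, target_y = rt$y)
  attr(rotated, "sampling_rate") <- 100
  m2 <- compute_metrics(rotated)
  expect_lt(max(abs(m2$tracking_angle - m0$tracking_angle)), 1e-6)
  expect_lt(max(abs(m2$distance - m0$distance)), 1e-6)
  # rotation about the origin preserves the cursor's distance from it
  expect_lt(max(abs(m2$excursion_difference - m0$excursion_difference)), 1e-6)
})

test_that("a 6 Hz confound moves tremor but barely moves the other metrics", {
  prof <- clean_profile("pd", tremor_amplitude = 0)
  s <- simulate_session(prof, small_cfg(1, 10), "p", seed = 13)
  m0 <- compute_metrics(s)
  s2 <- dplyr::mutate(s, cursor_x = cursor_x + 0.3 * sin(2 * pi * 6 * t))
  attr(s2, "sampling_rate") <- 100
  m1 <- compute_metrics(s2)
  expect_gt(mean(m1$tremor) - mean(m0$tremor), 0.25)
  for (col in c("distance", "vector_error", "slowness", "speed_difference",
                "excursion_difference")) {
    expect_lt(abs(mean(m1[[col]]) - mean(m0[[col]])) /
                max(abs(mean(m0[[col]])), 0.05), 0.05, label = col)
  }
})

test_that("displacement excursion mode reproduces the bin-magnitude reading", {
  n <- 400
  v <- 2
  line <- make_session(2 + (0:(n - 1)) * v / 100, rep(2, n))
  m <- compute_metrics(line, excursion_mode = "displacement")
  expect_equal(mean(m$excursion_difference), v / 100, tolerance = 1e-6)
})

test_that("metric correlation is 1 on the diagonal and flags degenerate input", {
  withr::with_seed(5, {
    n_subj <- 50
    fake <- purrr::map_dfr(seq_len(n_subj), function(i) {
      d <- tibble::tibble(subject_id = sprintf("s%02d", i),
                          group = "control", trial = 1L, epoch = 1:20)
      for (mc in metric_names()) d[[mc]] <- rnorm(20)
      d
    })
    mc <- metric_correlation(fake)
    diag_rows <- dplyr::filter(mc, metric_a == metric_b)
    expect_true(all(abs(diag_rows$r2 - 1) < 1e-12))
    off <- dplyr::filter(mc, metric_a != metric_b)
    expect_lt(stats::quantile(off$r2, 0.9), 0.15) # independent metrics decorrelate
  })
  degen <- tibble::tibble(subject_id = rep(c("a", "b", "c"), each = 4),
                          group = "control", trial = 1L, epoch = rep(1:4, 3))
  for (mc2 in metric_names()) degen[[mc2]] <- 1
  expect_warning(res <- metric_correlation(degen), "Zero-variance")
  expect_true(all(is.na(res$r2)))
})

test_that("slowness exponent calibration anchors at the 80th percentile speed", {
  speeds <- c(rep(10, 80), rep(50, 20))
  expect_equal(calibrate_slowness_b(speeds),
               -2 / stats::quantile(speeds, 0.8, names = FALSE))
  expect_error(calibrate_slowness_b(rep(0, 10)), "not positive")
})
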