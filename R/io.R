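#' Write and read session files
#'
#' A session is stored as a CSV with header
#' `trial,t,target_x,target_y,cursor_x,cursor_y,force` (seconds, cm, device
#' force units; cursor/force cells may be empty for target-only files) plus
#' a JSON sidecar (`<stem>.json`) carrying `subject_id`, `group_label`,
#' `sampling_rate`, `seed`, a profile echo, and `format_version`. Values are
#' written at full double precision so a write/read round trip is the
#' identity well below 1e-12.
#'
#' @param data Session tibble (see [simulate_session()]).
#' @param path CSV output path; the sidecar is written next to it.
#' @return `write_session()`: `path`, invisibly. `read_session()`: a session
#'   tibble with metadata attributes restored.
#' @export
write_session <- function(data, path) {
  cols <- c("trial", "t", "target_x", "target_y", "cursor_x", "cursor_y", "force")
  for (cl in setdiff(cols, names(data))) data[[cl]] <- NA_real_
  readr::write_csv(data[, cols], path, na = "")
  prof <- attr(data, "profile")
  meta <- list(
    format_version = "1.0",
    subject_id = if ("subject_id" %in% names(data)) data$subject_id[1] else
      attr(data, "subject_id"),
    group_label = if ("group" %in% names(data)) data$group[1] else NULL,
    sampling_rate = attr(data, "sampling_rate") %||% infer_fs(data$t),
    seed = attr(data, "seed"),
    profile = if (!is.null(prof)) unclass(prof) else NULL
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_session
#' @param path Path of the session CSV.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such session file: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial", "t", "target_x", "target_y")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Session file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_session_times(data)

  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!is.null(meta$subject_id)) {
    data <- dplyr::bind_cols(
      tibble::tibble(subject_id = meta$subject_id, .rows = nrow(data)), data)
  }
  if (!is.null(meta$group_label)) {
    data <- dplyr::mutate(data, group = meta$group_label,
                          .after = "subject_id")
  }
  out <- tibble::as_tibble(data)
  attr(out, "sampling_rate") <- meta$sampling_rate %||% infer_fs(out$t)
  attr(out, "seed") <- meta$seed
  if (!is.null(meta$profile)) attr(out, "profile") <- meta$profile
  out
}

# t must be strictly increasing and uniform within each trial block, and
# trial blocks must be contiguous; errors name the first offending CSV line.
validate_session_times <- function(data) {
  line_of <- function(i) i + 1L # header line offset
  tr <- data$trial
  r <- rle(as.character(tr))
  if (anyDuplicated(r$values) > 0) {
    starts <- cumsum(c(1L, head(r$lengths, -1)))
    bad <- which(duplicated(r$values))[1]
    abort(sprintf("Trial blocks are not contiguous: trial %s reappears (line %d).",
                  r$values[bad], line_of(starts[bad])))
  }
  for (id in unique(tr)) {
    idx <- which(tr == id)
    tt <- data$t[idx]
    d <- diff(tt)
    if (any(d <= 0)) {
      abort(sprintf("Time not strictly increasing in trial %s (line %d).",
                    id, line_of(idx[which(d <= 0)[1] + 1])))
    }
    if (length(d) > 1 && diff(range(d)) > 1e-9) {
      abort(sprintf("Non-uniform sampling interval in trial %s (line %d).",
                    id, line_of(idx[which.max(abs(d - stats::median(d))) + 1])))
    }
  }
  invisible(data)
}

#' Write and read metric tables
#'
#' Round-trippable CSV export of a [compute_metrics()] table.
#'
#' @param metrics Metric tibble.
#' @param path CSV path.
#' @return The path / the re-read tibble.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Serialize a fitted classifier to JSON
#'
#' Stores metric names, averaged and full-data hyperplane coefficients,
#' intercepts, the standardization parameters, per-iteration accuracies, and
#' the fit configuration, so MES can be recomputed without refitting.
#'
#' @param fit An `mes_classifier`.
#' @param path JSON output path.
#' @return `write_classifier()`: `path`, invisibly; `read_classifier()`: an
#'   `mes_classifier` (without the per-iteration coefficient matrix).
#' @export
write_classifier <- function(fit, path) {
  doc <- list(
    format_version = "1.0",
    metrics = fit$metrics,
    h = as.numeric(fit$h), h0 = fit$h0,
    h_full = as.numeric(fit$h_full), h0_full = fit$h0_full,
    center = as.numeric(fit$center), scale = as.numeric(fit$scale),
    accuracies = fit$accuracies,
    n_iter = fit$n_iter, cost = fit$cost,
    subsample = fit$subsample, average = fit$average,
    n_patient = fit$n_patient, n_control = fit$n_control,
    patient_label = fit$patient_label, control_label = fit$control_label,
    seed = fit$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- doc[setdiff(names(doc), "format_version")]
  names(fit$center) <- names(fit$scale) <- names(fit$h) <- fit$metrics
  names(fit$h_full) <- fit$metrics
  structure(fit, class = "mes_classifier")
}

#' Run configuration
#'
#' One document holding every pipeline tunable: path generation, filters,
#' classifier, evaluation, and the master seed. Round-trips losslessly
#' through YAML.
#'
#' @param path_cfg A [path_config()].
#' @param filt A [filter_spec()].
#' @param n_iter,cost,subsample,average Classifier settings (see
#'   [fit_mes_classifier()]).
#' @param n_boot Resamplings for [pooled_roc()].
#' @param percentiles Percentile grid for [percentile_correlation_scan()].
#' @param seed Master seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(path_cfg = path_config(), filt = filter_spec(),
                       n_iter = 100, cost = 1, subsample = "match",
                       average = "raw", n_boot = 100, percentiles = 1:100,
                       seed = 1L) {
  structure(list(path = unclass(path_cfg), filter = unclass(filt),
                 classifier = list(n_iter = n_iter, cost = cost,
                                   subsample = subsample, average = average),
                 evaluation = list(n_boot = n_boot,
                                   percentiles = as.integer(percentiles)),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path File path (YAML).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  doc$evaluation$percentiles <- as.integer(doc$evaluation$percentiles)
  doc$seed <- as.integer(doc$seed)
  structure(doc, class = "run_config")
}

# Restore the classed sub-configs of a run_config.
run_path_config <- function(cfg) {
  do.call(path_config, cfg$path[setdiff(names(cfg$path), character(0))])
}
run_filter_spec <- function(cfg) do.call(filter_spec, cfg$filter)
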