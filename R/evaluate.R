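#' Empirical percentile of an MES series
#'
#' Order statistic with linear interpolation between adjacent order
#' statistics (the convention of `stats::quantile(type = 7)`), so the 50th
#' percentile is the median and the 100th the maximum.
#'
#' @param x Numeric MES series.
#' @param p Percentile(s) in `[1, 100]`.
#' @return Numeric vector, one value per `p`.
#' @examples
#' mes_percentile(c(1, 2, 3), 50)
#' @export
mes_percentile <- function(x, p) {
  if (length(x) == 0) abort("Empty MES series.")
  if (any(p < 1 | p > 100)) abort("Percentile must lie in [1, 100].")
  quantile(x, p / 100, type = 7, names = FALSE)
}

#' Percentile-wise correlation of MES with a clinical score
#'
#' For each percentile 1..100, summarizes each subject's session MES at that
#' percentile and correlates the summaries with a clinical rating across
#' subjects (Spearman rank correlation). High percentiles emphasize each
#' subject's worst epochs; the percentile with maximal correlation shows
#' which part of the severity distribution clinicians' ratings track.
#'
#' @param mes_tbl Tibble with `subject_id` and `mes` columns (epoch-level).
#' @param scores Tibble with `subject_id` and the rating column.
#' @param score_col Name of the rating column in `scores`.
#' @param percentiles Integer grid (default 1:100).
#' @return A tibble of class `"percentile_scan"` with columns `percentile`,
#'   `rho`, `p_value`; attribute `best` holds the argmax-rho row.
#' @export
percentile_correlation_scan <- function(mes_tbl, scores, score_col = "score",
                                        percentiles = 1:100) {
  stopifnot("subject_id" %in% names(mes_tbl), "mes" %in% names(mes_tbl),
            "subject_id" %in% names(scores), score_col %in% names(scores))
  joined <- dplyr::inner_join(
    dplyr::group_by(mes_tbl, .data$subject_id) |>
      dplyr::summarise(mes_list = list(.data$mes), .groups = "drop"),
    scores, by = "subject_id"
  )
  if (nrow(joined) < 5) abort("Need >= 5 subjects with both MES and scores.")
  y <- joined[[score_col]]
  if (stats::sd(y) == 0) {
    warn("Clinical scores are constant: correlations undefined (NA).")
  }
  out <- purrr::map_dfr(percentiles, function(p) {
    xs <- purrr::map_dbl(joined$mes_list, mes_percentile, p = p)
    if (stats::sd(y) == 0 || stats::sd(xs) == 0) {
      return(tibble::tibble(percentile = p, rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(xs, y, method = "spearman", exact = FALSE))
    tibble::tibble(percentile = p, rho = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  best <- out[which.max(out$rho), ]
  structure(out, best = best, class = c("percentile_scan", class(out)))
}

#' Empirical ROC curve and area under it
#'
#' `roc_curve()` builds the empirical receiver operating characteristic of a
#' score that should be higher for the positive class; `roc_auc()`
#' integrates it by the trapezoid rule. With tied scores the curve steps
#' diagonally, which makes the trapezoid AUC equal the Mann-Whitney
#' statistic U/(n1 n2).
#'
#' @param pos Scores of the positive class (e.g. patient MES).
#' @param neg Scores of the negative class.
#' @return `roc_curve()`: tibble with `threshold`, `fpr`, `tpr`.
#'   `roc_auc()`: scalar in `[0, 1]`.
#' @examples
#' roc_auc(c(2, 3, 4), c(1, 2, 3))
#' @export
roc_curve <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0) abort("Both classes must be non-empty.")
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  # cumulative per-threshold counts: #(x >= th[k]) for descending thresholds
  cum_ge <- function(x) cumsum(tabulate(match(x, th), nbins = length(th)))
  tibble::tibble(
    threshold = c(Inf, th),
    fpr = c(0, cum_ge(neg) / length(neg)),
    tpr = c(0, cum_ge(pos) / length(pos))
  )
}

#' @rdname roc_curve
#' @export
roc_auc <- function(pos, neg) {
  if (length(unique(c(pos, neg))) == 1) {
    warn("Degenerate scores (all equal): AUC set to 0.5.")
    return(0.5)
  }
  rc <- roc_curve(pos, neg)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Pairwise patient-control AUC matrix
#'
#' For every (patient, control) subject pair, fits a dedicated Monte-Carlo
#' SVM classifier on that pair's epochs, scores both subjects' epochs with
#' it, and computes the ROC AUC of the two MES distributions (patient
#' positive). High AUC means the pair's epochs are separable at the
#' 1-second timescale.
#'
#' @param metrics Metric table with `subject_id` and `group` columns.
#' @param patient_group,control_group Group labels to pair.
#' @param n_iter Monte Carlo iterations per pair.
#' @param seed Optional master seed.
#' @param ... Passed on to [fit_mes_classifier()].
#' @return A tibble with columns `patient`, `control`, `auc`.
#' @export
pairwise_auc <- function(metrics, patient_group, control_group = "control",
                         n_iter = 25, seed = NULL, ...) {
  pats <- unique(metrics$subject_id[metrics$group == patient_group])
  cons <- unique(metrics$subject_id[metrics$group == control_group])
  if (length(pats) == 0 || length(cons) == 0) abort("Empty patient or control group.")
  grid <- tidyr::expand_grid(patient = pats, control = cons)
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(grid)) else
    as.list(derive_seeds(seed, nrow(grid)))
  grid$auc <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    d <- dplyr::filter(metrics,
                       .data$subject_id %in% c(grid$patient[i], grid$control[i]))
    fit <- fit_mes_classifier(d, patient_label = patient_group,
                              control_label = control_group,
                              n_iter = n_iter, seed = seeds[[i]], ...)
    scored <- mes(d, fit)
    roc_auc(scored$mes[scored$group == patient_group],
            scored$mes[scored$group == control_group])
  })
  grid
}

#' Pooled ROC with a resampling p-value
#'
#' Pools all epochs of a patient group against all control epochs, computes
#' the ROC AUC of their MES distributions, and attaches a label-resampling
#' p-value: labels are permuted `n_boot` times and the p-value is the
#' plus-one-corrected fraction of null AUCs at least as large as the
#' observed one, `p = (k + 1) / (n_boot + 1)`.
#'
#' @param group_mes,control_mes Numeric MES vectors.
#' @param n_boot Number of resamplings.
#' @param seed Optional integer seed.
#' @return A one-row tibble with `auc`, `p_value`, `n_boot`.
#' @export
pooled_roc <- function(group_mes, control_mes, n_boot = 100, seed = NULL) {
  if (length(group_mes) == 0 || length(control_mes) == 0) {
    abort("Both groups must be non-empty.")
  }
  if (n_boot < 20) warn("Fewer than 20 resamplings: the p-value is very coarse.")
  obs <- roc_auc(group_mes, control_mes)
  pooled <- c(group_mes, control_mes)
  n1 <- length(group_mes)
  k <- with_seed(seed, {
    sum(purrr::map_lgl(seq_len(n_boot), function(i) {
      idx <- sample(length(pooled), n1)
      suppressWarnings(roc_auc(pooled[idx], pooled[-idx])) >= obs
    }))
  })
  tibble::tibble(auc = obs, p_value = (k + 1) / (n_boot + 1), n_boot = n_boot)
}

#' Tremor-dominant / PIGD phenotype rule
#'
#' Classifies parkinsonian phenotype from clinical item means: the ratio of
#' the mean tremor item scores to the mean postural-instability/gait-
#' difficulty item scores. Ratio above 1.5 is tremor-dominant (`"TD"`),
#' below 1 is `"PIGD"`, between (inclusive) is `"mixed"`. A zero
#' denominator with nonzero tremor is `"TD"`; both zero is undefined (`NA`
#' with a warning).
#'
#' @param data Tibble of clinical scores.
#' @param tremor_col,pigd_col Columns holding the tremor and PIGD item
#'   means.
#' @return `data` with an added `phenotype` character column.
#' @examples
#' phenotype_classify(tibble::tibble(tremor_item_mean = c(2, 1.2, 0.5),
#'                                   pigd_item_mean = c(1, 1, 1)))
#' @export
phenotype_classify <- function(data, tremor_col = "tremor_item_mean",
                               pigd_col = "pigd_item_mean") {
  tm <- data[[tremor_col]]
  pg <- data[[pigd_col]]
  if (any(pg < 0 | tm < 0, na.rm = TRUE)) abort("Item means must be nonnegative.")
  ratio <- ifelse(pg == 0, ifelse(tm > 0, Inf, NaN), tm / pg)
  if (any(is.nan(ratio))) warn("Both item means zero for some rows: phenotype NA.")
  dplyr::mutate(data, phenotype = dplyr::case_when(
    is.nan(ratio) ~ NA_character_,
    ratio > 1.5 ~ "TD",
    ratio < 1 ~ "PIGD",
    TRUE ~ "mixed"
  ))
}

#' Long-format metric-weight table across subjects
#'
#' Collects the metric weights of per-subject classifiers into one long
#' tibble, with group-mean weights attached, for profile plots and external
#' statistics.
#'
#' @param fits Named list of `mes_classifier`s (names = subject ids).
#' @param groups Character vector parallel to `fits` giving each subject's
#'   group; defaults to each fit's `patient_label`.
#' @param plane Which stored plane to take weights from.
#' @return A tibble with columns `subject_id`, `group`, `metric`, `weight`;
#'   attribute `group_means` holds the per-group mean weights.
#' @export
weight_profile_table <- function(fits, groups = NULL,
                                 plane = c("averaged", "full")) {
  plane <- match.arg(plane)
  if (length(fits) == 0) abort("No classifiers supplied.")
  metric_sets <- purrr::map(fits, "metrics")
  if (length(unique(purrr::map_chr(metric_sets, paste, collapse = ","))) > 1) {
    abort("Classifiers use different metric sets.")
  }
  groups <- groups %||% purrr::map_chr(fits, "patient_label")
  ids <- names(fits) %||% paste0("s", seq_along(fits))
  out <- purrr::pmap_dfr(list(fits, ids, groups), function(fit, id, gr) {
    dplyr::bind_cols(tibble::tibble(subject_id = id, group = gr,
                                    .rows = length(fit$metrics)),
                     metric_weights(fit, plane = plane))
  })
  gm <- out |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(weight = mean(.data$weight), .groups = "drop")
  attr(out, "group_means") <- gm
  out
}
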