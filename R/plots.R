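#' Plot a tracking trial: target vs cursor
#'
#' @param session Session tibble.
#' @param trials Which trials to show (default: first).
#' @return A ggplot.
#' @export
plot_session <- function(session, trials = 1) {
  d <- dplyr::filter(session, .data$trial %in% trials)
  ggplot2::ggplot(d) +
    ggplot2::geom_path(ggplot2::aes(.data$target_x, .data$target_y),
                       colour = "grey40") +
    ggplot2::geom_path(ggplot2::aes(.data$cursor_x, .data$cursor_y),
                       colour = "#7A0177", alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(ggplot2::vars(.data$trial)) +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  title = "Target (grey) and cursor (purple) traces")
}

# Gaussian kernel smoothing for display only; analyses always use raw MES.
gaussian_smooth <- function(x, sd = 2) {
  if (sd <= 0 || length(x) < 3) return(x)
  half <- ceiling(3 * sd)
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Plot an MES timeline
#'
#' Epoch-by-epoch Motor Error Scores with an optional Gaussian smooth
#' (display only — analyses always use the raw scores).
#'
#' @param mes_tbl Tibble with `epoch` and `mes` columns (and optionally
#'   `trial`).
#' @param smooth_sd SD of the display smoothing kernel, in epochs; 0
#'   disables it.
#' @return A ggplot.
#' @export
plot_mes_timeline <- function(mes_tbl, smooth_sd = 2) {
  d <- mes_tbl
  if (!"trial" %in% names(d)) d$trial <- 1
  d <- d |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(mes_smooth = gaussian_smooth(.data$mes, smooth_sd)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mes), colour = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mes_smooth), colour = "#7A0177") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trial), scales = "free_x") +
    ggplot2::labs(x = "epoch (s)", y = "MES",
                  title = "Motor Error Score per 1-s epoch")
}

#' @export
autoplot.percentile_scan <- function(object, ...) {
  best <- attr(object, "best")
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("rho", "p_value"),
                           names_to = "stat", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$percentile, .data$value,
                                  colour = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best$percentile, linetype = 3) +
    ggplot2::labs(x = "MES percentile", y = NULL,
                  title = sprintf("Max rho = %.3f at percentile %d",
                                  best$rho, best$percentile))
}

#' Plot metric-weight profiles
#'
#' Per-subject weight profiles (thin lines) with group means (thick lines),
#' one panel per group.
#'
#' @param weights A [weight_profile_table()] result.
#' @return A ggplot.
#' @export
plot_weight_profiles <- function(weights) {
  gm <- attr(weights, "group_means")
  p <- ggplot2::ggplot(weights,
                       ggplot2::aes(.data$metric, .data$weight,
                                    group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.35, colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(y = "metric weight", x = NULL)
  if (!is.null(gm)) {
    p <- p + ggplot2::geom_line(data = gm,
                                ggplot2::aes(.data$metric, .data$weight,
                                             group = .data$group),
                                linewidth = 1.1, colour = "#7A0177")
  }
  p
}

#' @export
autoplot.mes_classifier <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$metric, .data$weight)) +
    ggplot2::geom_col(fill = "#7A0177") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(y = "metric weight", x = NULL,
                  title = sprintf("%s vs %s (accuracy %.3f)",
                                  object$patient_label, object$control_label,
                                  mean(object$accuracies)))
}

#' Plot a ROC curve
#'
#' @param rc A [roc_curve()] tibble.
#' @return A ggplot.
#' @export
plot_roc <- function(rc) {
  ggplot2::ggplot(rc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#7A0177") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}
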