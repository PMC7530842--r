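#' Signed distance from points to a hyperplane
#'
#' The Motor Error Score formula: for a metric vector `m` and a hyperplane
#' with normal coefficients `h` and intercept `h0`,
#' \deqn{SS = (h \cdot m + h_0) / |h|,}
#' the signed Euclidean distance from `m` to the plane, positive on the side
#' `h` points toward.
#'
#' @param x Numeric matrix (rows = points) or vector (one point).
#' @param h Coefficient vector (no intercept).
#' @param h0 Intercept.
#' @return Numeric vector of signed distances.
#' @examples
#' hyperplane_distance(c(1, 0), h = c(2, 0), h0 = -1) # 0.5
#' @export
hyperplane_distance <- function(x, h, h0) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nh <- sqrt(sum(h^2))
  if (nh == 0) abort("Zero coefficient vector: hyperplane undefined.")
  as.numeric(x %*% h + h0) / nh
}

# Extract (w, b) of a fitted linear e1071 SVM in input space, oriented so
# that scores X %*% w + b are on average larger for rows where `positive`
# is TRUE (computed on the training data; independent of e1071's internal
# label ordering).
svm_plane <- function(model, X, positive) {
  w <- drop(crossprod(model$coefs, model$SV))
  b <- -model$rho
  score <- as.numeric(X %*% w) + b
  if (mean(score[positive]) < mean(score[!positive])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

stratified_split <- function(y, train_frac = 0.8) {
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    train[sample(idx, floor(train_frac * length(idx)))] <- TRUE
  }
  train
}

#' Fit the Monte-Carlo-averaged Motor Error Score classifier
#'
#' Separates a patient's (or patient group's) metric epochs from pooled
#' control epochs with a linear SVM, using a Monte Carlo subsampling
#' protocol to neutralize class imbalance: on each of `n_iter` iterations
#' the control pool is subsampled without replacement to match the patient
#' epoch count (1:1), the balanced set is split 80/20 (stratified), a linear
#' SVM (cost 1, hyperparameters fixed a priori) is fit on the 80% and its
#' accuracy recorded on the held-out 20%. The final hyperplane is the
#' arithmetic mean of the per-iteration coefficient vectors and intercepts,
#' sign-corrected so patient epochs score positive. A "full-data" plane,
#' fit once on all epochs, is also stored and is the default for computing
#' MES (maximizing the data behind each score).
#'
#' Metrics are z-scored with pooled-control mean/SD before fitting; the
#' scaling is stored in the returned object so [mes()] is self-contained.
#'
#' @param data Metric table from [compute_metrics()] with a label column.
#' @param patient_label,control_label Values of `label_col` defining the
#'   two classes.
#' @param label_col Column holding class labels (default `"group"`).
#' @param metrics Metric columns to use (default: all eight present).
#' @param n_iter Monte Carlo iterations.
#' @param cost SVM regularization parameter C.
#' @param subsample `"match"` (subsample controls to the patient epoch
#'   count) or a numeric divisor applied to the control pool size.
#' @param average `"raw"` (mean of coefficients as-is) or `"normalized"`
#'   (each iteration's plane scaled to unit normal before averaging).
#' @param scale_ref Optional metric table providing the standardization
#'   reference; defaults to the control rows of `data`.
#' @param seed Optional integer seed governing all subsampling and splits.
#' @return An object of class `"mes_classifier"`: averaged and full-data
#'   hyperplanes, per-iteration coefficients and test accuracies, the
#'   stored standardization, and the fit configuration.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(3, 2, 0, path_config(n_trials = 2, trial_duration = 6),
#'                        seed = 1)
#' m <- compute_metrics(coh)
#' fit <- fit_mes_classifier(m, patient_label = "pd", n_iter = 10, seed = 1)
#' glance(fit)
#' }
#' @export
fit_mes_classifier <- function(data, patient_label, control_label = "control",
                               label_col = "group",
                               metrics = intersect(metric_names(), names(data)),
                               n_iter = 100, cost = 1,
                               subsample = "match",
                               average = c("raw", "normalized"),
                               scale_ref = NULL, seed = NULL) {
  average <- match.arg(average)
  if (!label_col %in% names(data)) abort(sprintf("No label column '%s'.", label_col))
  lab <- data[[label_col]]
  pat <- data[lab == patient_label, , drop = FALSE]
  con <- data[lab == control_label, , drop = FALSE]
  if (nrow(pat) == 0 || nrow(con) == 0) {
    abort("Both classes must be present: check `patient_label`/`control_label`.")
  }
  drop_na <- function(d) d[stats::complete.cases(d[, metrics, drop = FALSE]), ,
                           drop = FALSE]
  pat <- drop_na(pat); con <- drop_na(con)
  subsample_patient <- FALSE
  if (nrow(pat) > nrow(con) && identical(subsample, "match")) {
    if (nrow(pat) > 1.1 * nrow(con)) {
      abort(paste("Patient pool larger than control pool: subsampling to 1:1 is",
                  "impossible. Swap the roles or pass a numeric `subsample` factor."))
    }
    # a slight excess (e.g. one trial truncated differently) is absorbed by
    # subsampling the patient side down to the control pool size as well
    warn("Patient pool slightly larger than control pool; subsampling patients to match.")
    subsample_patient <- TRUE
  }

  ref <- scale_ref %||% con
  centre <- purrr::map_dbl(metrics, ~ mean(ref[[.x]]))
  scale_ <- purrr::map_dbl(metrics, ~ stats::sd(ref[[.x]]))
  names(centre) <- names(scale_) <- metrics
  if (any(scale_ == 0 | !is.finite(scale_))) {
    abort("Zero-variance metric in the scaling reference; exclude it first.")
  }
  std <- function(d) {
    sweep(sweep(as.matrix(d[, metrics, drop = FALSE]), 2, centre), 2, scale_, "/")
  }
  Xp <- std(pat); Xc <- std(con)
  n_pat <- if (subsample_patient) nrow(Xc) else nrow(Xp)
  n_keep <- if (identical(subsample, "match")) n_pat else
    max(1L, round(nrow(Xc) / subsample))
  if (n_keep > nrow(Xc)) {
    warn("Subsample size exceeds control pool; using the whole pool.")
    n_keep <- nrow(Xc)
  }
  if (min(nrow(Xp), n_keep) < 30) {
    warn("Fewer than 30 epochs per class after subsampling; accuracies will be noisy.")
  }

  with_seed(seed, {
    p <- length(metrics)
    W <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, metrics))
    b <- numeric(n_iter)
    acc <- numeric(n_iter)
    counts <- matrix(NA_integer_, n_iter, 2,
                     dimnames = list(NULL, c("patient", "control")))
    for (i in seq_len(n_iter)) {
      Xpi <- if (subsample_patient) Xp[sample(nrow(Xp), n_pat), , drop = FALSE]
             else Xp
      Xci <- Xc[sample(nrow(Xc), n_keep), , drop = FALSE]
      X <- rbind(Xpi, Xci)
      ypos <- c(rep(TRUE, nrow(Xpi)), rep(FALSE, nrow(Xci)))
      counts[i, ] <- c(sum(ypos), sum(!ypos))
      tr <- stratified_split(ypos)
      yf <- factor(ifelse(ypos, "patient", "control"), levels = c("control", "patient"))
      model <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "linear",
                          cost = cost, scale = FALSE)
      pl <- svm_plane(model, X[tr, , drop = FALSE], ypos[tr])
      if (average == "normalized") {
        nw <- sqrt(sum(pl$w^2))
        pl$w <- pl$w / nw
        pl$b <- pl$b / nw
      }
      W[i, ] <- pl$w
      b[i] <- pl$b
      acc[i] <- mean(predict(model, X[!tr, , drop = FALSE]) == yf[!tr])
    }
    h <- colMeans(W)
    h0 <- mean(b)
    # orientation: patient epochs must score higher on average
    if (mean(as.numeric(Xp %*% h) + h0) < mean(as.numeric(Xc %*% h) + h0)) {
      h <- -h
      h0 <- -h0
    }

    Xall <- rbind(Xp, Xc)
    yall <- c(rep(TRUE, nrow(Xp)), rep(FALSE, nrow(Xc)))
    yfall <- factor(ifelse(yall, "patient", "control"),
                    levels = c("control", "patient"))
    full_model <- e1071::svm(Xall, yfall, kernel = "linear", cost = cost,
                             scale = FALSE)
    full <- svm_plane(full_model, Xall, yall)

    structure(list(
      metrics = metrics,
      h = h, h0 = h0,
      h_full = full$w, h0_full = full$b,
      coefs = W, intercepts = b,
      accuracies = acc,
      iter_class_counts = counts,
      center = centre, scale = scale_,
      n_iter = n_iter, cost = cost,
      subsample = subsample, average = average,
      n_patient = nrow(Xp), n_control = nrow(Xc), n_subsampled = n_keep,
      patient_label = patient_label, control_label = control_label,
      seed = seed
    ), class = "mes_classifier")
  })
}

#' @export
print.mes_classifier <- function(x, ...) {
  cat(sprintf("<mes_classifier> %s vs %s | %d metrics | %d iterations\n",
              x$patient_label, x$control_label, length(x$metrics), x$n_iter))
  cat(sprintf("  test accuracy %.3f (SD %.3f); %d patient vs %d control epochs (%d/iter)\n",
              mean(x$accuracies), stats::sd(x$accuracies),
              x$n_patient, x$n_control, x$n_subsampled))
  invisible(x)
}

#' @rdname fit_mes_classifier
#' @param x An `mes_classifier`.
#' @param plane `"averaged"` (the Monte-Carlo mean hyperplane) or `"full"`
#'   (the all-data fit).
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per metric — `metric`,
#'   `coefficient`, `weight`.
#' @export
tidy.mes_classifier <- function(x, plane = c("averaged", "full"), ...) {
  plane <- match.arg(plane)
  h <- if (plane == "averaged") x$h else x$h_full
  tibble::tibble(
    metric = x$metrics,
    coefficient = unname(h),
    weight = unname(h^2 / sum(h^2))
  )
}

#' @rdname fit_mes_classifier
#' @return `glance()`: a one-row tibble with `accuracy_mean`, `accuracy_sd`,
#'   `n_iter`, `n_metrics`, `n_patient`, `n_control`.
#' @export
glance.mes_classifier <- function(x, ...) {
  tibble::tibble(
    accuracy_mean = mean(x$accuracies),
    accuracy_sd = stats::sd(x$accuracies),
    n_iter = x$n_iter,
    n_metrics = length(x$metrics),
    n_patient = x$n_patient,
    n_control = x$n_control
  )
}

#' Score epochs with a fitted classifier (Motor Error Scores)
#'
#' Standardizes each epoch's metric vector with the scaling stored in the
#' classifier and computes its signed Euclidean distance to the hyperplane
#' ([hyperplane_distance()]). Positive scores indicate motor dysfunction
#' (the patient side of the plane).
#'
#' @param data Metric table containing the classifier's metric columns.
#' @param fit An [fit_mes_classifier()] object.
#' @param plane `"full"` (default; the all-data fit used for scoring) or
#'   `"averaged"` (the Monte-Carlo mean plane).
#' @return `data` with an added `mes` column.
#' @export
mes <- function(data, fit, plane = c("full", "averaged")) {
  plane <- match.arg(plane)
  missing_cols <- setdiff(fit$metrics, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Metric-set mismatch; data lacks: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- sweep(sweep(as.matrix(data[, fit$metrics, drop = FALSE]), 2, fit$center),
             2, fit$scale, "/")
  h <- if (plane == "full") fit$h_full else fit$h
  h0 <- if (plane == "full") fit$h0_full else fit$h0
  dplyr::mutate(data, mes = hyperplane_distance(X, h, h0))
}

#' Metric weights of a hyperplane
#'
#' The relative contribution of each metric to the classifier: the square of
#' its coefficient divided by the sum of squared coefficients,
#' \deqn{w_i = h_i^2 / \sum_j h_j^2.}
#' Weights are nonnegative and sum to one; the intercept is excluded.
#'
#' @param fit An `mes_classifier`, or a bare numeric coefficient vector.
#' @param plane Which stored plane to use (classifier input only).
#' @return A tibble with columns `metric` and `weight`.
#' @examples
#' metric_weights(c(3, 4)) # 9/25, 16/25
#' @export
metric_weights <- function(fit, plane = c("averaged", "full")) {
  plane <- match.arg(plane)
  if (is.numeric(fit)) {
    h <- fit
    nm <- names(h) %||% paste0("m", seq_along(h))
  } else {
    h <- if (plane == "averaged") fit$h else fit$h_full
    nm <- fit$metrics
  }
  ss <- sum(h^2)
  if (ss == 0) abort("Zero coefficient vector: weights undefined.")
  tibble::tibble(metric = nm, weight = unname(h^2 / ss))
}

#' Label-shuffling control for the MES classifier
#'
#' Re-runs the full Monte-Carlo classification after randomly permuting the
#' class labels across subjects (or across epochs if no `subject_id` column
#' is present). For a real class difference the shuffled accuracy collapses
#' to chance; this is the specificity control for the classifier.
#'
#' @inheritParams fit_mes_classifier
#' @param permutation Optional explicit permutation of the subjects (test
#'   hook); the identity permutation reproduces the unshuffled fit.
#' @param ... Passed on to [fit_mes_classifier()].
#' @return An `mes_classifier` with `$shuffled = TRUE`.
#' @export
shuffled_label_control <- function(data, patient_label,
                                   control_label = "control",
                                   label_col = "group",
                                   permutation = NULL, seed = NULL, ...) {
  keep <- data[[label_col]] %in% c(patient_label, control_label)
  d <- data[keep, , drop = FALSE]
  shuffle_seed <- if (is.null(seed)) NULL else derive_seeds(seed, 2)[1]
  fit_seed <- if (is.null(seed)) NULL else derive_seeds(seed, 2)[2]
  if ("subject_id" %in% names(d)) {
    subj <- d |>
      dplyr::distinct(.data$subject_id, .keep_all = FALSE) |>
      dplyr::pull(.data$subject_id)
    labels <- d[[label_col]][match(subj, d$subject_id)]
    perm <- permutation %||% with_seed(shuffle_seed, sample(length(subj)))
    new_lab <- labels[perm]
    d[[label_col]] <- new_lab[match(d$subject_id, subj)]
  } else {
    perm <- permutation %||% with_seed(shuffle_seed, sample(nrow(d)))
    d[[label_col]] <- d[[label_col]][perm]
  }
  fit <- fit_mes_classifier(d, patient_label = patient_label,
                            control_label = control_label,
                            label_col = label_col, seed = fit_seed, ...)
  fit$shuffled <- TRUE
  fit
}

#' Refit the classifier with a metric excluded
#'
#' Repeats the identical Monte-Carlo protocol in the reduced metric space,
#' e.g. dropping `tremor` to quantify how much the classification leans on
#' the tremor envelope.
#'
#' @inheritParams fit_mes_classifier
#' @param exclude Metric name(s) to drop.
#' @param ... Passed on to [fit_mes_classifier()].
#' @return An `mes_classifier` with `$excluded` recording the dropped
#'   metrics.
#' @export
metric_excluded_fit <- function(data, patient_label, exclude,
                                control_label = "control",
                                metrics = intersect(metric_names(), names(data)),
                                ...) {
  unknown <- setdiff(exclude, metrics)
  if (length(unknown) > 0) {
    abort(paste0("Unknown metric(s): ", paste(unknown, collapse = ", ")))
  }
  kept <- setdiff(metrics, exclude)
  if (length(kept) < 2) abort("At least two metrics must remain after exclusion.")
  fit <- fit_mes_classifier(data, patient_label = patient_label,
                            control_label = control_label, metrics = kept, ...)
  fit$excluded <- exclude
  fit
}

#' Within-subject two-state classifier
#'
#' Discriminates two conditions of the same subject (e.g. stimulation On vs
#' Off) with the same Monte-Carlo linear-SVM protocol, the larger state
#' subsampled to balance, plus a label-shuffled control run. Standardization
#' uses the pooled epochs of both states.
#'
#' @param data_a,data_b Metric tables for the two states of one subject.
#' @param n_iter Monte Carlo iterations.
#' @param n_shuffle Number of independent label permutations for the
#'   shuffled control; the reported chance level is their pooled mean (a
#'   single permutation's accuracy retains that permutation's sampling
#'   noise).
#' @param seed Optional integer seed.
#' @param ... Passed on to [fit_mes_classifier()].
#' @return A list of class `"two_state_report"`: `fit` (an
#'   `mes_classifier`) and `shuffled` (a list of shuffled-label
#'   `mes_classifier`s).
#' @export
two_state_classifier <- function(data_a, data_b, n_iter = 100, n_shuffle = 5,
                                 seed = NULL, ...) {
  if (nrow(data_a) < 30 || nrow(data_b) < 30) {
    warn("Fewer than 30 epochs in a state; accuracies will be noisy.")
  }
  a <- dplyr::mutate(data_a, .state = "state_a")
  b <- dplyr::mutate(data_b, .state = "state_b")
  combined <- dplyr::bind_rows(a, b)
  # patient class = the smaller state, so 1:1 subsampling stays feasible
  pat_lab <- if (nrow(a) <= nrow(b)) "state_a" else "state_b"
  con_lab <- setdiff(c("state_a", "state_b"), pat_lab)
  seeds <- if (is.null(seed)) rep(list(NULL), n_shuffle + 1) else
    as.list(derive_seeds(seed, n_shuffle + 1))
  fit <- fit_mes_classifier(combined, patient_label = pat_lab,
                            control_label = con_lab, label_col = ".state",
                            n_iter = n_iter, scale_ref = combined,
                            seed = seeds[[1]], ...)
  combined_noid <- combined[, setdiff(names(combined), "subject_id"), drop = FALSE]
  shuf <- purrr::map(seq_len(n_shuffle), function(k) {
    shuffled_label_control(combined_noid, patient_label = pat_lab,
                           control_label = con_lab, label_col = ".state",
                           n_iter = n_iter, scale_ref = combined,
                           seed = seeds[[k + 1]], ...)
  })
  structure(list(fit = fit, shuffled = shuf), class = "two_state_report")
}

#' @export
print.two_state_report <- function(x, ...) {
  shuf_acc <- unlist(purrr::map(x$shuffled, "accuracies"))
  cat(sprintf("<two_state_report> accuracy %.3f vs shuffled %.3f (%d permutations)\n",
              mean(x$fit$accuracies), mean(shuf_acc), length(x$shuffled)))
  invisible(x)
}

#' @rdname two_state_classifier
#' @param x A `two_state_report`.
#' @return `glance()`: one-row tibble with the true and shuffled accuracies.
#' @export
glance.two_state_report <- function(x, ...) {
  shuf_acc <- unlist(purrr::map(x$shuffled, "accuracies"))
  tibble::tibble(
    accuracy_mean = mean(x$fit$accuracies),
    accuracy_sd = stats::sd(x$fit$accuracies),
    shuffled_mean = mean(shuf_acc),
    shuffled_sd = stats::sd(shuf_acc),
    n_iter = x$fit$n_iter,
    n_shuffle = length(x$shuffled)
  )
}
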