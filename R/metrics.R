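#' Classification metrics at a probability cut-point
#'
#' Sensitivity is the fraction of case subjects called case (predicted
#' probability above the threshold); specificity the fraction of controls
#' called control; accuracy the overall fraction correct.
#'
#' @param data A data frame of scored subjects (e.g. from
#'   [predict_prob()]).
#' @param spec An [analysis_spec()]; its `class_case` defines the positive
#'   class and `prob_threshold` the cut-point.
#' @param prob Name of the probability column.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `auc` and the class counts.
#' @export
classification_metrics <- function(data, spec, prob = ".prob") {
  probs <- data[[prob]]
  keep <- !is.na(probs)
  metrics_vec(probs[keep], outcome_vector(data$label[keep], spec),
              threshold = spec$prob_threshold)
}

#' @rdname classification_metrics
#' @param probs Numeric vector of case probabilities.
#' @param y 0/1 outcome vector (1 = case).
#' @param threshold Probability cut-point.
#' @export
metrics_vec <- function(probs, y, threshold = 0.5) {
  if (length(unique(y)) < 2) {
    abort("Both classes must be present to compute classification metrics.")
  }
  pred <- as.numeric(probs > threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  tibble(
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / sum(y == 1),
    specificity = tn / sum(y == 0),
    auc = auc_vec(probs, y),
    n_case = sum(y == 1),
    n_control = sum(y == 0)
  )
}

# Bare-numeric metric vector (accuracy, sensitivity, specificity, auc)
# for tight resampling loops; assumes both classes present.
metrics_fast <- function(probs, y, threshold) {
  pred <- probs > threshold
  case <- y == 1
  n1 <- sum(case)
  n0 <- length(y) - n1
  tp <- sum(pred & case)
  tn <- sum(!pred & !case)
  r <- rank(probs, ties.method = "average")
  c(accuracy = (tp + tn) / length(y),
    sensitivity = tp / n1,
    specificity = tn / n0,
    auc = (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0))
}

#' Area under the ROC curve
#'
#' The rank statistic P(score of a random case > score of a random
#' control), with ties counted one half -- the Mann-Whitney U divided by
#' `n_case * n_control`. Midranks make this exact under ties.
#'
#' @param probs Numeric scores.
#' @param y 0/1 outcomes (1 = case).
#' @return AUC in [0, 1].
#' @export
auc_vec <- function(probs, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present to compute AUC.")
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auc_vec
#' @param data A data frame of scored subjects.
#' @param spec An [analysis_spec()].
#' @param prob Probability column name.
#' @export
auc <- function(data, spec, prob = ".prob") {
  probs <- data[[prob]]
  keep <- !is.na(probs)
  auc_vec(probs[keep], outcome_vector(data$label[keep], spec))
}

#' ROC curve points
#'
#' Thresholds at every distinct score, descending; the curve runs from
#' (0, 0) to (1, 1) with both coordinates non-decreasing, and its
#' trapezoidal area equals [auc_vec()] (ties contribute half).
#'
#' @inheritParams auc_vec
#' @return A tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve_vec <- function(probs, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present for a ROC curve.")
  ord <- order(probs, decreasing = TRUE)
  s <- probs[ord]
  yy <- y[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last row of each tied block
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, cumsum(yy == 0)[last] / n0),
    tpr = c(0, cumsum(yy == 1)[last] / n1)
  )
}

#' @rdname roc_curve_vec
#' @param data A data frame of scored subjects.
#' @param spec An [analysis_spec()].
#' @param prob Probability column name.
#' @export
roc_curve <- function(data, spec, prob = ".prob") {
  probs <- data[[prob]]
  keep <- !is.na(probs)
  roc_curve_vec(probs[keep], outcome_vector(data$label[keep], spec))
}

#' Odds ratio at two standard deviations from the mean
#'
#' For a z-standardized predictor, `exp(2 |beta|)` is the odds ratio of a
#' two-standard-deviation move along the feature, the per-feature impact
#' summary reported alongside each coefficient.
#'
#' @param beta Logistic coefficient(s) per standardized unit.
#' @return Odds ratio(s), always >= 1.
#' @export
odds_ratio_2sd <- function(beta) {
  exp(2 * abs(beta))
}

#' Univariate Wilcoxon rank-sum screen with Bonferroni correction
#'
#' Two-sided rank-sum test of each feature between the two classes, on that
#' feature's complete cases; exact p-values for combined n <= 20, normal
#' approximation with tie correction otherwise. The Bonferroni-adjusted
#' p-value is `min(1, p * m)` with `m` the number of features tested.
#'
#' @param data A feature table.
#' @param spec An [analysis_spec()].
#' @param features Features to test (default: all).
#' @return A tibble with per-feature `statistic`, `p.value`, `p.adjusted`,
#'   ordered by p-value.
#' @export
univariate_screen <- function(data, spec, features = NULL) {
  data <- restrict_contrast(data, spec)
  features <- features %||% feature_names(data)
  assert_features_exist(data, features)
  m <- length(features)
  rows <- purrr::map(features, function(f) {
    xc <- data[[f]][data$label == spec$class_control]
    xa <- data[[f]][data$label == spec$class_case]
    xc <- xc[!is.na(xc)]
    xa <- xa[!is.na(xa)]
    if (length(xc) < 2 || length(xa) < 2) {
      abort(paste0("Need >= 2 non-missing values per class for '", f, "'."))
    }
    exact <- (length(xc) + length(xa)) <= 20
    wt <- suppressWarnings(
      wilcox.test(xa, xc, exact = exact, correct = TRUE)
    )
    tibble(feature = f, n_control = length(xc), n_case = length(xa),
           statistic = unname(wt$statistic), p.value = wt$p.value)
  })
  out <- bind_rows(rows)
  out$p.adjusted <- pmin(1, out$p.value * m)
  arrange(out, .data$p.value)
}
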