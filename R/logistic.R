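#' Fit a diagnostic logistic regression on named features
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares with step halving (the deviance never increases). Subjects with
#' missing data on any model feature are excluded first (complete-case
#' rule); the case class is coded 1, the control class 0. Convergence is
#' declared when the score vanishes (max |X'(y - p)| < 1e-8) or the
#' relative deviance change falls below 1e-10. Perfect separation is
#' flagged: the model is marked non-converged and its coefficients should
#' not be trusted.
#'
#' @param data A feature table.
#' @param features Character vector of feature names; empty for an
#'   intercept-only model.
#' @param spec An [analysis_spec()] naming the two classes.
#' @return A `panel_logit` object; see [tidy()] and [glance()] methods.
#' @export
fit_logistic <- function(data, features, spec) {
  data <- restrict_contrast(data, spec)
  data <- complete_case_subset(data, features)
  y <- outcome_vector(data$label, spec)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, features, drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("Singular design: collinear feature(s) ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- .irls_fit(X, y)
  if (fit$separated) {
    warn(paste0("Perfect separation detected; coefficients are not trusted ",
                "(features: ", paste(features, collapse = ", "), ")."))
  }
  beta <- drop(fit$beta)
  se <- drop(fit$se)
  z <- beta / se
  coef_tbl <- tibble(
    term = colnames(X),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z))),
    or_2sd = c(NA_real_, odds_ratio_2sd(unname(beta)[-1]))
  )
  structure(list(
    features = features,
    intercept = unname(beta[1]),
    coefficients = setNames(unname(beta[-1]), features),
    coef_table = coef_tbl,
    n_control = sum(y == 0),
    n_case = sum(y == 1),
    deviance = fit$deviance,
    converged = fit$converged,
    separated = fit$separated,
    iterations = fit$iterations,
    class_control = spec$class_control,
    class_case = spec$class_case,
    prob_threshold = spec$prob_threshold,
    subject_ids = data$subject_id
  ), class = "panel_logit")
}

#' Predicted case probabilities
#'
#' Applies the logistic link `1 / (1 + exp(-(b0 + sum(beta_j * z_j))))` to
#' every subject of the table. Subjects missing any model feature cannot be
#' scored and get `NA` with `scorable = FALSE`.
#'
#' @param model A `panel_logit`.
#' @param data A feature table carrying the model's features.
#' @return A tibble with `subject_id`, `label`, `.prob`, `scorable`.
#' @export
predict_prob <- function(model, data) {
  assert_features_exist(data, model$features)
  if (length(model$features) == 0) {
    eta <- rep(model$intercept, nrow(data))
    ok <- rep(TRUE, nrow(data))
  } else {
    Z <- as.matrix(data[, model$features, drop = FALSE])
    ok <- stats::complete.cases(Z)
    eta <- model$intercept + drop(Z %*% model$coefficients)
    eta[!ok] <- NA_real_
  }
  tibble(subject_id = data$subject_id, label = data$label,
         .prob = plogis(eta), scorable = ok)
}

#' @export
print.panel_logit <- function(x, ...) {
  cat("Logistic diagnostic model: ", x$class_control, " (0) vs ",
      x$class_case, " (1)\n", sep = "")
  cat("  n = ", x$n_control, " + ", x$n_case, ", features: ",
      if (length(x$features)) paste(x$features, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  if (!x$converged) cat("  ! not converged",
                        if (x$separated) " (separation)", "\n", sep = "")
  print(x$coef_table)
  invisible(x)
}

#' Tidy a fitted panel model
#'
#' One row per term: coefficient, Wald standard error / z / two-sided p,
#' and the odds ratio at two standard deviations from the mean
#' (`exp(2 |beta|)`, meaningful for z-standardized predictors).
#'
#' @param x A `panel_logit`.
#' @param ... Unused.
#' @method tidy panel_logit
#' @export
tidy.panel_logit <- function(x, ...) {
  x$coef_table
}

#' @rdname tidy.panel_logit
#' @method glance panel_logit
#' @export
glance.panel_logit <- function(x, ...) {
  tibble(n_control = x$n_control, n_case = x$n_case,
         n_features = length(x$features), deviance = x$deviance,
         converged = x$converged, separated = x$separated,
         iterations = x$iterations)
}

#' Serialize / read a fitted model as JSON
#'
#' @param model A `panel_logit`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    class_control = model$class_control, class_case = model$class_case,
    features = model$features, intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    coef_table = model$coef_table,
    n_control = model$n_control, n_case = model$n_case,
    converged = model$converged, separated = model$separated
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
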