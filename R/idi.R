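#' Integrated discrimination improvement between nested models
#'
#' Pencina's estimator on paired predicted probabilities for the same
#' subjects: IDI = (mean probability gain over events) - (mean probability
#' gain over nonevents), with standard error
#' `sqrt(s_e^2 / n_e + s_ne^2 / n_ne)` from the within-group sample SDs of
#' the per-subject probability differences, `z = IDI / SE`, and a
#' two-sided normal p-value.
#'
#' @param probs_old,probs_new Predicted probabilities of the nested and
#'   extended model for the same subjects, in the same order.
#' @param y 0/1 event indicator (1 = event/case).
#' @return An `idi_result`: `idi`, `se`, `z`, `p`, group sizes and a
#'   `degenerate` flag (both group SDs zero but idi != 0).
#' @export
idi_statistic <- function(probs_old, probs_new, y) {
  stopifnot(length(probs_old) == length(probs_new),
            length(probs_old) == length(y))
  y <- as.numeric(y)
  ev <- y == 1
  if (!any(ev) || all(ev)) abort("Both groups must be non-empty.")
  d <- probs_new - probs_old
  idi <- mean(d[ev]) - mean(d[!ev])
  se <- sqrt(var(d[ev]) / sum(ev) + var(d[!ev]) / sum(!ev))
  degenerate <- FALSE
  if (is.na(se) || se == 0) {
    if (abs(idi) < .Machine$double.eps^0.5) {
      z <- 0
      p <- 1
      se <- 0
    } else {
      z <- sign(idi) * Inf
      p <- 0
      se <- 0
      degenerate <- TRUE
    }
  } else {
    z <- idi / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(idi = idi, se = se, z = z, p = p,
                 n_events = sum(ev), n_nonevents = sum(!ev),
                 degenerate = degenerate),
            class = "idi_result")
}

#' @export
print.idi_result <- function(x, ...) {
  cat(sprintf("IDI = %.4f (SE %.4f), z = %.3f, p = %.4g  [%d events / %d nonevents]%s\n",
              x$idi, x$se, x$z, x$p, x$n_events, x$n_nonevents,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' @method tidy idi_result
#' @export
tidy.idi_result <- function(x, ...) {
  tibble(idi = x$idi, se = x$se, statistic = x$z, p.value = x$p,
         n_events = x$n_events, n_nonevents = x$n_nonevents,
         degenerate = x$degenerate)
}

# Restrict a subject-keyed fold assignment to `ids`; when absent or
# invalid on the restricted set (a fold whose training rows hold one class
# only), redraw deterministically, up to 10 attempts.
resolve_folds <- function(y, ids, k, folds, seed) {
  fold <- if (!is.null(folds)) unname(folds[ids]) else NULL
  for (attempt in 0:10) {
    if (!is.null(fold) && folds_valid(y, fold, k)) return(fold)
    if (attempt == 10) break
    fold <- make_folds(y, k, seed + attempt)
  }
  abort("Could not build cross-validation folds with both classes in every training set.")
}

folds_valid <- function(y, fold, k) {
  if (anyNA(fold)) return(FALSE)
  for (f in seq_len(k)) {
    tr <- y[fold != f]
    if (length(unique(tr)) < 2) return(FALSE)
  }
  TRUE
}

# Out-of-fold probabilities for one feature set on a fixed complete-case
# population. `data` must already be restricted to those subjects.
oof_probs <- function(data, features, spec, fold) {
  y <- outcome_vector(data$label, spec)
  X <- cbind(1, as.matrix(data[, features, drop = FALSE]))
  probs <- rep(NA_real_, nrow(data))
  for (f in seq_len(spec$k_folds)) {
    test <- fold == f
    if (!any(test)) next
    fit <- .irls_fit(X[!test, , drop = FALSE], y[!test])
    probs[test] <- plogis(drop(X[test, , drop = FALSE] %*% fit$beta))
  }
  probs
}

#' Cross-validated out-of-fold probabilities
#'
#' Every subject is scored by the model fit on the other k - 1 folds.
#' Folds are stratified by class and reproducible from the seed; the same
#' subject-keyed fold assignment can be supplied to score nested and
#' extended models on identical folds, as the IDI comparison requires.
#'
#' @param data A feature table (restricted to the contrast's classes).
#' @param features Feature names of the model (empty = intercept-only).
#' @param spec An [analysis_spec()].
#' @param folds Optional named integer vector (names = subject ids) fixing
#'   the fold of every subject.
#' @param seed Seed used when folds must be (re)drawn.
#' @return A tibble with `subject_id`, `label`, `.prob`, `fold`.
#' @export
cv_probabilities <- function(data, features, spec, folds = NULL,
                             seed = NULL) {
  data <- restrict_contrast(data, spec)
  data <- complete_case_subset(data, features)
  y <- outcome_vector(data$label, spec)
  seed <- seed %||% stage_seed(spec$rng_seed, "forward")
  fold <- resolve_folds(y, data$subject_id, spec$k_folds, folds, seed)
  tibble(subject_id = data$subject_id, label = data$label,
         .prob = oof_probs(data, features, spec, fold), fold = fold)
}

# IDI of adding `extra` to `parent`, both scored by out-of-fold CV
# probabilities on the complete cases of the union feature set.
idi_compare <- function(data, parent, extra, spec, folds = NULL,
                        seed = NULL) {
  all_feats <- union(parent, extra)
  cc <- complete_case_subset(data, all_feats)
  y <- outcome_vector(cc$label, spec)
  seed <- seed %||% stage_seed(spec$rng_seed, "forward")
  fold <- resolve_folds(y, cc$subject_id, spec$k_folds, folds, seed)
  p_old <- oof_probs(cc, parent, spec, fold)
  p_new <- oof_probs(cc, all_feats, spec, fold)
  res <- idi_statistic(p_old, p_new, y)
  res$n_subjects <- nrow(cc)
  res
}
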