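#' Build the a-posteriori validation split (APIS)
#'
#' Subjects outside the feature-selection set that have complete data on
#' the final model's features form the APIS set. A seeded simple random
#' sample of m APIS subjects joins the feature-selection set to form the
#' calibration set, with m chosen so that |calibration| : |test| matches
#' the target ratio: m = round((ratio * |APIS| - |FS|) / (1 + ratio)),
#' clamped to the feasible range with a warning. The remaining APIS
#' subjects are the held-out test set.
#'
#' @param data The full feature table (all subjects of the contrast's two
#'   classes, before any missingness exclusion), typically the standardized
#'   full cohort.
#' @param model The final `panel_logit` (fixes the feature filter).
#' @param fs_ids Subject ids of the feature-selection set.
#' @param spec An [analysis_spec()].
#' @return A `split_plan`: `fs_ids`, `apis_ids`, `calibration_ids`,
#'   `test_ids`, `m`, `seed`.
#' @export
build_apis <- function(data, model, fs_ids, spec) {
  data <- restrict_contrast(data, spec)
  feats <- model$features
  outside <- data[!data$subject_id %in% fs_ids, , drop = FALSE]
  if (length(feats) > 0) {
    ok <- complete.cases(outside[, feats, drop = FALSE])
  } else {
    ok <- rep(TRUE, nrow(outside))
  }
  apis_ids <- outside$subject_id[ok]
  seed <- stage_seed(spec$rng_seed, "split")
  A <- length(apis_ids)
  F_ <- length(fs_ids)
  if (A == 0) {
    warn("APIS set is empty: validation degenerates to bootstrap-only on the feature-selection set.")
    plan <- list(fs_ids = fs_ids, apis_ids = character(),
                 calibration_ids = fs_ids, test_ids = character(),
                 m = 0L, seed = seed)
    return(structure(plan, class = "split_plan"))
  }
  ratio <- spec$calibration_test_ratio
  m <- round((ratio * A - F_) / (1 + ratio))
  m_clamped <- min(max(m, 0L), A - 1L)
  if (m_clamped != m) {
    warn(paste0("Target calibration:test ratio ", ratio,
                ":1 unreachable; APIS sample clamped to ", m_clamped, "."))
  }
  m <- m_clamped
  sampled <- withr::with_seed(seed, sample(apis_ids, m))
  plan <- list(
    fs_ids = fs_ids, apis_ids = apis_ids,
    calibration_ids = c(fs_ids, sampled),
    test_ids = setdiff(apis_ids, sampled),
    m = m, seed = seed
  )
  structure(plan, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan: ", length(x$fs_ids), " feature-selection + ",
      length(x$apis_ids), " APIS subjects\n", sep = "")
  cat("  calibration ", length(x$calibration_ids), " : test ",
      length(x$test_ids), "\n", sep = "")
  invisible(x)
}

#' Recalibrate a fixed feature set on the calibration population
#'
#' Refits the logistic coefficients on the calibration subjects only; the
#' feature set is never reselected. Coefficient signs are compared with the
#' pre-calibration fit: a sign flip would mean the effect detected during
#' feature selection was not conserved, and is logged with a warning.
#'
#' @param data The full feature table.
#' @param model The final `panel_logit` from feature selection.
#' @param split A `split_plan` from [build_apis()].
#' @param spec An [analysis_spec()].
#' @return The calibrated `panel_logit`; `sign_flips` attribute lists any
#'   flipped terms.
#' @export
calibrate_model <- function(data, model, split, spec) {
  cal <- data[data$subject_id %in% split$calibration_ids, , drop = FALSE]
  out <- fit_logistic(cal, model$features, spec)
  flips <- model$features[sign(out$coefficients) != sign(model$coefficients) &
                            model$coefficients != 0 & out$coefficients != 0]
  if (length(flips) > 0) {
    warn(paste0("Coefficient sign flip after calibration: ",
                paste(flips, collapse = ", ")))
  }
  attr(out, "sign_flips") <- flips
  out
}

#' Bootstrap performance evaluation of a fixed model
#'
#' The calibrated model is applied once to the evaluation population; each
#' of `n_bootstrap` class-stratified resamples (with replacement) then
#' recomputes accuracy, sensitivity, specificity and AUC from the fixed
#' predicted probabilities -- the model is never refit. Reported are the
#' point metrics on the original population, the bootstrap means, and
#' 2.5/97.5 percentile confidence intervals. A degenerate resample (an
#' undefined metric) is redrawn, at most 10 times.
#'
#' @param model A fitted `panel_logit`.
#' @param data A feature table (the evaluation population, e.g. the
#'   calibration subjects); subjects missing a model feature are excluded.
#' @param spec An [analysis_spec()].
#' @param seed Seed for the resampling (defaults to a stream derived from
#'   `spec$rng_seed`).
#' @return A `panel_eval`: tibble with one row per metric (`estimate`,
#'   `boot_mean`, `ci_low`, `ci_high`); ROC points of the point evaluation
#'   in the `roc` attribute.
#' @export
bootstrap_evaluate <- function(model, data, spec, seed = NULL) {
  data <- restrict_contrast(data, spec)
  data <- complete_case_subset(data, model$features)
  scored <- predict_prob(model, data)
  probs <- scored$.prob
  y <- outcome_vector(scored$label, spec)
  point <- metrics_vec(probs, y, spec$prob_threshold)
  idx_case <- which(y == 1)
  idx_ctrl <- which(y == 0)
  seed <- seed %||% stage_seed(spec$rng_seed, "bootstrap")
  boot <- matrix(NA_real_, nrow = spec$n_bootstrap, ncol = 4,
                 dimnames = list(NULL, c("accuracy", "sensitivity",
                                         "specificity", "auc")))
  withr::with_seed(seed, {
    for (b in seq_len(spec$n_bootstrap)) {
      mb <- NULL
      for (try in 1:10) {
        take <- c(sample(idx_case, length(idx_case), replace = TRUE),
                  sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
        mb <- metrics_fast(probs[take], y[take], spec$prob_threshold)
        if (!anyNA(mb)) break
        mb <- NULL
      }
      if (is.null(mb)) abort("Bootstrap resample degenerate after 10 redraws.")
      boot[b, ] <- mb
    }
  })
  res <- tibble(
    metric = colnames(boot),
    estimate = unlist(point[1, colnames(boot)]),
    boot_mean = colMeans(boot),
    ci_low = apply(boot, 2, quantile, probs = 0.025, names = FALSE),
    ci_high = apply(boot, 2, quantile, probs = 0.975, names = FALSE)
  )
  class(res) <- c("panel_eval", class(res))
  attr(res, "roc") <- roc_curve_vec(probs, y)
  attr(res, "n_case") <- sum(y == 1)
  attr(res, "n_control") <- sum(y == 0)
  attr(res, "n_bootstrap") <- spec$n_bootstrap
  res
}

#' @method tidy panel_eval
#' @export
tidy.panel_eval <- function(x, ...) as_tibble(x)

#' @rdname tidy.panel_logit
#' @method glance panel_eval
#' @export
glance.panel_eval <- function(x, ...) {
  tibble(n_case = attr(x, "n_case"), n_control = attr(x, "n_control"),
         n_bootstrap = attr(x, "n_bootstrap"))
}

#' Random-model null experiment
#'
#' Draws `spec$n_random_models` random feature sets of the same size as
#' the proposed model (uniformly, without replacement within a set) from
#' the eligible pool, fits each on the calibration population, and
#' evaluates it with [bootstrap_evaluate()]. The chance probability is the
#' proportion of random models whose bootstrap-mean accuracy (resp. AUC)
#' strictly exceeds the proposed model's; 2.5/97.5 percentile bands of the
#' null distributions are reported for the density plot. Aborts if more
#' than 10% of the random models cannot be fit.
#'
#' @param model The calibrated proposed `panel_logit`.
#' @param data The full feature table.
#' @param spec An [analysis_spec()].
#' @param calibration_ids Subjects to fit/evaluate on (the calibration
#'   set).
#' @param feature_pool Eligible features (default: all features of
#'   `data`, i.e. those surviving the missingness filter).
#' @param proposed_eval Optional precomputed [bootstrap_evaluate()] result
#'   for the proposed model on the same population.
#' @return A `null_experiment`: `densities` (one row per random model with
#'   its bootstrap-mean accuracy and AUC), `p_accuracy`, `p_auc`,
#'   percentile `bands`, and the proposed model's means.
#' @export
random_model_null <- function(model, data, spec, calibration_ids,
                              feature_pool = NULL,
                              proposed_eval = NULL) {
  size <- length(model$features)
  if (size == 0) abort("The proposed model has no features.")
  pool <- feature_pool %||% feature_names(data)
  cal <- data[data$subject_id %in% calibration_ids, , drop = FALSE]
  if (is.null(proposed_eval)) {
    proposed_eval <- bootstrap_evaluate(model, cal, spec)
  }
  seed <- stage_seed(spec$rng_seed, "null")
  draws <- withr::with_seed(seed, {
    lapply(seq_len(spec$n_random_models), function(i) sample(pool, size))
  })
  rows <- vector("list", spec$n_random_models)
  failed <- 0L
  for (i in seq_len(spec$n_random_models)) {
    rows[[i]] <- tryCatch({
      rm_fit <- fit_logistic(cal, draws[[i]], spec)
      ev <- bootstrap_evaluate(rm_fit, cal, spec, seed = seed + i)
      tibble(model_id = i,
             mean_accuracy = ev$boot_mean[ev$metric == "accuracy"],
             mean_auc = ev$boot_mean[ev$metric == "auc"])
    }, error = function(e) e)
    if (inherits(rows[[i]], "error")) failed <- failed + 1L
    if (failed > 0.1 * spec$n_random_models) {
      abort(paste0("More than 10% of random models unfittable; last error: ",
                   conditionMessage(rows[[i]])))
    }
  }
  ok <- !vapply(rows, inherits, logical(1), "error")
  densities <- bind_rows(rows[ok])
  prop_acc <- proposed_eval$boot_mean[proposed_eval$metric == "accuracy"]
  prop_auc <- proposed_eval$boot_mean[proposed_eval$metric == "auc"]
  bands <- tibble(
    metric = c("accuracy", "auc"),
    q025 = c(quantile(densities$mean_accuracy, 0.025, names = FALSE),
             quantile(densities$mean_auc, 0.025, names = FALSE)),
    q975 = c(quantile(densities$mean_accuracy, 0.975, names = FALSE),
             quantile(densities$mean_auc, 0.975, names = FALSE))
  )
  structure(list(
    densities = densities,
    p_accuracy = mean(densities$mean_accuracy > prop_acc),
    p_auc = mean(densities$mean_auc > prop_auc),
    bands = bands,
    proposed = tibble(metric = c("accuracy", "auc"),
                      boot_mean = c(prop_acc, prop_auc)),
    n_failed = failed
  ), class = "null_experiment")
}

#' @export
print.null_experiment <- function(x, ...) {
  cat("Random-model null experiment (", nrow(x$densities), " models)\n",
      sep = "")
  cat(sprintf("  P(random accuracy > proposed) = %.4f\n", x$p_accuracy))
  cat(sprintf("  P(random AUC > proposed)      = %.4f\n", x$p_auc))
  print(x$bands)
  invisible(x)
}

#' @method tidy null_experiment
#' @export
tidy.null_experiment <- function(x, ...) x$densities
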