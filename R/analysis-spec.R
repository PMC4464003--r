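#' Analysis specification for one binary contrast
#'
#' Bundles every tunable of the pipeline for one two-class comparison
#' (e.g. healthy controls vs Alzheimer's disease). Defaults follow the
#' published methodology: a 20% per-class missingness cutoff, Pearson
#' |rho| > 0.8 at p < 0.05 for correlated-feature merging, 1,000 evolved
#' five-feature models over 300 generations, IDI gating at p < 0.05 on the
#' same cross-validation folds, 1,000 bootstrap resamples, 1,000 random
#' null models, and a 4:1 calibration:test size ratio.
#'
#' @param class_control,class_case Label names of the control-like and
#'   disease-progressed class. The case class is coded 1 in every logistic
#'   fit and defines sensitivity.
#' @param k_folds Cross-validation folds used both for GA fitness and for
#'   the IDI comparisons (3 or 4 in the source methodology).
#' @param missing_threshold Per-class missing-fraction cutoff; strictly
#'   "more than" drops a feature.
#' @param correlation_threshold,correlation_p Pearson threshold and p-value
#'   for frequency merging.
#' @param idi_p Significance level for the IDI gates.
#' @param n_ga_models Number of independent GA runs (final chromosomes).
#' @param ga_generations Generations per GA run.
#' @param model_chromosome_size Features per chromosome.
#' @param ga_population,ga_tournament,ga_mutation GA internals: population
#'   size, tournament size for parent selection, and per-gene mutation
#'   probability.
#' @param fs_max_candidates Forward selection walks at most this many
#'   top-ranked features.
#' @param fs_stop_at_failure Stop the forward walk at the first failing
#'   candidate instead of skipping it.
#' @param prob_threshold Probability cut-point for the accuracy /
#'   sensitivity / specificity decision rule.
#' @param n_bootstrap Bootstrap resamples for performance intervals.
#' @param n_random_models Random models in the null experiment.
#' @param calibration_test_ratio Target |calibration| / |test| size ratio.
#' @param rng_seed Master seed; every stage derives its own stream from it.
#' @return An object of class `analysis_spec`.
#' @export
analysis_spec <- function(class_control, class_case,
                          k_folds = 3,
                          missing_threshold = 0.20,
                          correlation_threshold = 0.8,
                          correlation_p = 0.05,
                          idi_p = 0.05,
                          n_ga_models = 1000,
                          ga_generations = 300,
                          model_chromosome_size = 5,
                          ga_population = 50,
                          ga_tournament = 2,
                          ga_mutation = 0.02,
                          fs_max_candidates = 50,
                          fs_stop_at_failure = FALSE,
                          prob_threshold = 0.5,
                          n_bootstrap = 1000,
                          n_random_models = 1000,
                          calibration_test_ratio = 4.0,
                          rng_seed = 1L) {
  spec <- list(
    class_control = as.character(class_control),
    class_case = as.character(class_case),
    k_folds = as.integer(k_folds),
    missing_threshold = missing_threshold,
    correlation_threshold = correlation_threshold,
    correlation_p = correlation_p,
    idi_p = idi_p,
    n_ga_models = as.integer(n_ga_models),
    ga_generations = as.integer(ga_generations),
    model_chromosome_size = as.integer(model_chromosome_size),
    ga_population = as.integer(ga_population),
    ga_tournament = as.integer(ga_tournament),
    ga_mutation = ga_mutation,
    fs_max_candidates = as.integer(fs_max_candidates),
    fs_stop_at_failure = isTRUE(fs_stop_at_failure),
    prob_threshold = prob_threshold,
    n_bootstrap = as.integer(n_bootstrap),
    n_random_models = as.integer(n_random_models),
    calibration_test_ratio = calibration_test_ratio,
    rng_seed = as.integer(rng_seed)
  )
  validate_analysis_spec(spec)
  structure(spec, class = "analysis_spec")
}

validate_analysis_spec <- function(spec) {
  if (identical(spec$class_control, spec$class_case)) {
    abort("`class_control` and `class_case` must differ.")
  }
  counts <- c("k_folds", "n_ga_models", "ga_generations",
              "model_chromosome_size", "ga_population", "ga_tournament",
              "fs_max_candidates", "n_bootstrap", "n_random_models")
  for (nm in counts) {
    if (spec[[nm]] < 1) abort(paste0("`", nm, "` must be positive."))
  }
  fracs <- c("missing_threshold", "correlation_threshold", "correlation_p",
             "idi_p", "ga_mutation", "prob_threshold")
  for (nm in fracs) {
    if (spec[[nm]] <= 0 || spec[[nm]] >= 1) {
      abort(paste0("`", nm, "` must lie in (0, 1)."))
    }
  }
  if (spec$calibration_test_ratio <= 0) {
    abort("`calibration_test_ratio` must be positive.")
  }
  invisible(spec)
}

#' @export
print.analysis_spec <- function(x, ...) {
  cat("Analysis spec: ", x$class_control, " (control) vs ", x$class_case,
      " (case)\n", sep = "")
  cat("  k-folds ", x$k_folds, ", GA ", x$n_ga_models, " runs x ",
      x$ga_generations, " generations, chromosome size ",
      x$model_chromosome_size, "\n", sep = "")
  cat("  missingness cutoff ", x$missing_threshold, ", merge |rho| > ",
      x$correlation_threshold, " (p < ", x$correlation_p, "), IDI p < ",
      x$idi_p, "\n", sep = "")
  cat("  bootstrap ", x$n_bootstrap, ", random models ", x$n_random_models,
      ", calibration:test ", x$calibration_test_ratio, ":1, seed ",
      x$rng_seed, "\n", sep = "")
  invisible(x)
}
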