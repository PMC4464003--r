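# Numeric view of a contrast: subjects x features matrix (NA = missing),
# 0/1 outcome, feature names. Built once and shared by all GA runs.
contrast_matrix <- function(data, spec) {
  data <- restrict_contrast(data, spec)
  feats <- feature_names(data)
  list(
    X = as.matrix(data[, feats, drop = FALSE]),
    y = outcome_vector(data$label, spec),
    features = feats,
    subject_ids = data$subject_id
  )
}

# One GA run on the numeric view. Classic wrapper GA over fixed-size
# feature subsets: tournament selection, uniform crossover with repair to
# distinct genes, per-gene mutation, elitism keeping the single best.
# Fitness = stratified k-fold CV accuracy of the chromosome's logistic
# model on its complete-case subjects.
evolve_one_impl <- function(cm, spec, run_seed) {
  nf <- ncol(cm$X)
  size <- spec$model_chromosome_size
  if (nf < size) abort("Fewer features than the chromosome size.")
  withr::with_seed(run_seed, {
    fold <- make_folds(cm$y, spec$k_folds, sample.int(2^30, 1))
    res <- .ga_run(cm$X, cm$y, fold, spec$k_folds, spec$prob_threshold,
                   spec$ga_population, size, spec$ga_generations,
                   spec$ga_mutation, spec$ga_tournament)
    list(genes = sort(cm$features[res$genes]),
         fitness = res$fitness,
         generations_run = spec$ga_generations)
  })
}

#' Evolve one fixed-size logistic model with a genetic algorithm
#'
#' Runs a single GA search: a population of fixed-size feature subsets
#' (chromosomes) evolves by tournament selection, uniform crossover,
#' per-gene mutation and single-best elitism, scored by stratified k-fold
#' cross-validated accuracy of the subset's logistic regression. Subjects
#' missing any chromosome feature are excluded from that chromosome's
#' fitness (complete-case rule); folds whose training rows hold one class
#' are skipped, and a chromosome with no scorable fold gets fitness 0.
#' Fully reproducible from `run_seed`.
#'
#' @param data A filtered, standardized feature table.
#' @param spec An [analysis_spec()].
#' @param run_seed Integer seed for this run.
#' @return A list with `genes` (feature names), `fitness`,
#'   `generations_run`.
#' @export
evolve_one <- function(data, spec, run_seed) {
  evolve_one_impl(contrast_matrix(data, spec), spec, run_seed)
}

#' GA wrapper search: many runs and the feature-frequency table
#'
#' Performs `spec$n_ga_models` independent GA runs (run r is seeded
#' `rng_seed + r`) and tallies how often each feature appears in the final
#' chromosomes. Frequencies sum to `n_ga_models * model_chromosome_size`.
#' Individual failed runs are skipped; the batch aborts if more than 10%
#' fail.
#'
#' @param data A filtered, standardized feature table.
#' @param spec An [analysis_spec()].
#' @return A `ga_result`: `models` (one row per run: `run`, `genes`
#'   list-column, `fitness`) and `frequencies` (per-feature `count` and
#'   `mean_fitness`).
#' @export
ga_search <- function(data, spec) {
  cm <- contrast_matrix(data, spec)
  runs <- vector("list", spec$n_ga_models)
  failures <- 0L
  for (r in seq_len(spec$n_ga_models)) {
    runs[[r]] <- tryCatch(
      evolve_one_impl(cm, spec, spec$rng_seed + r),
      error = function(e) e
    )
    if (inherits(runs[[r]], "error")) failures <- failures + 1L
    if (failures > 0.1 * spec$n_ga_models) {
      abort(paste0("More than 10% of GA runs failed; last error: ",
                   conditionMessage(runs[[r]])))
    }
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  models <- tibble(
    run = which(ok),
    genes = lapply(runs[ok], `[[`, "genes"),
    fitness = vapply(runs[ok], `[[`, numeric(1), "fitness")
  )
  long <- tibble(
    feature = unlist(models$genes),
    fitness = rep(models$fitness, lengths(models$genes))
  )
  freqs <- long |>
    group_by(.data$feature) |>
    summarise(count = dplyr::n(), mean_fitness = mean(.data$fitness)) |>
    arrange(desc(.data$count), desc(.data$mean_fitness), .data$feature)
  structure(list(models = models, frequencies = freqs,
                 n_failed = sum(!ok)),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA search: ", nrow(x$models), " final chromosomes (",
      x$n_failed, " failed runs)\n", sep = "")
  cat("Top features:\n")
  print(head(x$frequencies, 10))
  invisible(x)
}

#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) {
  x$frequencies
}
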