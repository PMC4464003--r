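#' Correlation-merged feature-frequency ranking
#'
#' Features are walked in descending raw GA frequency (ties broken by
#' higher mean fitness, then name). Each retained feature absorbs every
#' not-yet-absorbed lower-frequency feature whose Pearson correlation with
#' it exceeds the threshold (|rho| > 0.8 at p < 0.05 by default, two-sided
#' t-test on complete pairs); the absorbed feature leaves the ranking and
#' its frequency transfers to the absorber, so the total frequency is
#' conserved. Pairs with fewer than 3 complete observations are skipped
#' with a warning (the correlation p is undefined). The ranking is then
#' ordered by merged frequency.
#'
#' @param freqs A `ga_result` or a tibble with columns `feature`, `count`
#'   (and optionally `mean_fitness`).
#' @param data The feature table the GA searched (used for correlations).
#' @param spec An [analysis_spec()].
#' @return A `feature_ranking`: tibble with `rank`, `feature`, `raw_freq`,
#'   `merged_freq`, `mean_fitness`, `absorbed` (list-column); the merge log
#'   (discarded, absorbed_into, rho, p) is in the `merge_log` attribute.
#' @export
merge_correlated <- function(freqs, data, spec) {
  if (inherits(freqs, "ga_result")) freqs <- freqs$frequencies
  if (!"mean_fitness" %in% names(freqs)) freqs$mean_fitness <- NA_real_
  data <- restrict_contrast(data, spec)
  ord <- order(-freqs$count, -freqs$mean_fitness, freqs$feature)
  feats <- freqs$feature[ord]
  raw <- freqs$count[ord]
  mfit <- freqs$mean_fitness[ord]
  k <- length(feats)
  X <- as.matrix(data[, feats, drop = FALSE])

  merged <- raw
  absorbed_by <- rep(NA_integer_, k)
  absorbed_lists <- vector("list", k)
  log_rows <- list()
  skipped <- 0L
  for (i in seq_len(k)) {
    if (!is.na(absorbed_by[i])) next
    for (j in seq_len(k)) {
      if (j <= i || !is.na(absorbed_by[j])) next
      pair_ok <- !is.na(X[, i]) & !is.na(X[, j])
      n_pair <- sum(pair_ok)
      if (n_pair < 3) { skipped <- skipped + 1L; next }
      rho <- cor(X[pair_ok, i], X[pair_ok, j])
      if (is.na(rho) || abs(rho) <= spec$correlation_threshold) next
      p <- cor_pvalue(rho, n_pair)
      if (p >= spec$correlation_p) next
      absorbed_by[j] <- i
      merged[i] <- merged[i] + raw[j]
      absorbed_lists[[i]] <- c(absorbed_lists[[i]], feats[j])
      log_rows[[length(log_rows) + 1L]] <- tibble(
        discarded = feats[j], absorbed_into = feats[i],
        rho = rho, p = p, n = n_pair
      )
    }
  }
  if (skipped > 0) {
    warn(paste0(skipped, " feature pair(s) skipped: fewer than 3 complete ",
                "observations (correlation p undefined)."))
  }
  keep <- is.na(absorbed_by)
  out <- tibble(
    feature = feats[keep], raw_freq = raw[keep], merged_freq = merged[keep],
    mean_fitness = mfit[keep],
    absorbed = lapply(absorbed_lists[keep], function(x) x %||% character())
  )
  out <- arrange(out, desc(.data$merged_freq), desc(.data$mean_fitness),
                 .data$feature)
  out$rank <- seq_len(nrow(out))
  out <- select(out, "rank", dplyr::everything())
  class(out) <- c("feature_ranking", class(out))
  attr(out, "merge_log") <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(discarded = character(), absorbed_into = character(),
           rho = numeric(), p = numeric(), n = integer())
  out
}

# Two-sided p for a Pearson correlation via t = rho * sqrt((n-2)/(1-rho^2)).
cor_pvalue <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' @method tidy feature_ranking
#' @export
tidy.feature_ranking <- function(x, ...) {
  out <- as_tibble(x)
  out$absorbed <- vapply(out$absorbed, paste, character(1), collapse = ";")
  out
}

#' IDI-gated forward selection along the merged ranking
#'
#' Walks the ranking from the top (at most `spec$fs_max_candidates`
#' features), starting from the intercept-only model. Each candidate is
#' added only if the cross-validated IDI of parent + candidate over the
#' parent is positive with p below `spec$idi_p`; both models are scored by
#' out-of-fold probabilities on the complete cases of the extended feature
#' set, using one subject-keyed fold assignment drawn per pass. Failing
#' candidates are skipped and the walk continues (set
#' `spec$fs_stop_at_failure` to stop instead). The selected model is
#' refit on all complete-case subjects of its features.
#'
#' @param ranking A [merge_correlated()] ranking.
#' @param data The filtered, standardized feature table.
#' @param spec An [analysis_spec()].
#' @return A `panel_logit` with the selection audit (one row per
#'   candidate: idi, z, p, decision) in the `audit` attribute.
#' @export
forward_select <- function(ranking, data, spec) {
  if (nrow(ranking) == 0) abort("Empty ranking: nothing to select from.")
  data <- restrict_contrast(data, spec)
  seed <- stage_seed(spec$rng_seed, "forward")
  folds <- setNames(make_folds(outcome_vector(data$label, spec),
                               spec$k_folds, seed), data$subject_id)
  candidates <- head(ranking$feature, spec$fs_max_candidates)
  model_feats <- character()
  audit <- list()
  for (cand in candidates) {
    res <- tryCatch(
      idi_compare(data, model_feats, cand, spec, folds = folds, seed = seed),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      audit[[length(audit) + 1L]] <- tibble(
        candidate = cand, idi = NA_real_, z = NA_real_, p = NA_real_,
        n_subjects = NA_integer_, decision = "error")
      next
    }
    include <- res$idi > 0 && res$p < spec$idi_p && !res$degenerate
    audit[[length(audit) + 1L]] <- tibble(
      candidate = cand, idi = res$idi, z = res$z, p = res$p,
      n_subjects = res$n_subjects,
      decision = if (include) "included" else "skipped")
    if (include) {
      model_feats <- c(model_feats, cand)
    } else if (spec$fs_stop_at_failure) {
      break
    }
  }
  if (length(model_feats) == 0) {
    warn("No feature passed the IDI gate; returning the intercept-only model.")
  }
  model <- fit_logistic(data, model_feats, spec)
  attr(model, "audit") <- bind_rows(audit)
  model
}

#' IDI-z backward elimination
#'
#' Each cycle computes, for every feature f in the current model, the
#' cross-validated IDI of the full model over the model without f (i.e.
#' the contribution of f's addition to its parent). The feature with the
#' smallest IDI z-score is removed provided that score is not significant
#' (p > `spec$idi_p`); the model is refit and the cycle repeats until every
#' remaining feature is significant. Comparisons within a cycle share one
#' fold assignment.
#'
#' @param model A `panel_logit` from [forward_select()].
#' @param data The filtered, standardized feature table.
#' @param spec An [analysis_spec()].
#' @return The reduced `panel_logit`, with the elimination audit in the
#'   `audit` attribute.
#' @export
backward_eliminate <- function(model, data, spec) {
  data <- restrict_contrast(data, spec)
  seed <- stage_seed(spec$rng_seed, "backward")
  folds <- setNames(make_folds(outcome_vector(data$label, spec),
                               spec$k_folds, seed), data$subject_id)
  feats <- model$features
  audit <- list()
  cycle <- 0L
  while (length(feats) > 0) {
    cycle <- cycle + 1L
    stats_f <- purrr::map(feats, function(f) {
      res <- idi_compare(data, setdiff(feats, f), f, spec, folds = folds,
                         seed = seed)
      tibble(cycle = cycle, feature = f, idi = res$idi, z = res$z, p = res$p)
    })
    stats_f <- bind_rows(stats_f)
    worst <- which.min(stats_f$z)
    removable <- stats_f$p[worst] > spec$idi_p
    stats_f$decision <- "kept"
    if (removable) stats_f$decision[worst] <- "removed"
    audit[[cycle]] <- stats_f
    if (!removable) break
    feats <- setdiff(feats, stats_f$feature[worst])
  }
  out <- fit_logistic(data, feats, spec)
  attr(out, "audit") <- if (length(audit)) bind_rows(audit) else
    tibble(cycle = integer(), feature = character(), idi = numeric(),
           z = numeric(), p = numeric(), decision = character())
  out
}
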