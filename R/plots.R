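#' Plot the ROC curve of an evaluation
#'
#' @param object A `panel_eval` from [bootstrap_evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot panel_eval
#' @export
autoplot.panel_eval <- function(object, ...) {
  roc <- attr(object, "roc")
  auc_val <- object$estimate[object$metric == "auc"]
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c6fa8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", auc_val)) +
    ggplot2::theme_minimal()
}

#' Plot the random-model null densities
#'
#' Density of the bootstrap-mean accuracy and AUC of the random models,
#' with the proposed model's values marked; the proposed model should sit
#' outside the null's 95% band when its performance is not due to chance.
#'
#' @param object A `null_experiment` from [random_model_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot null_experiment
#' @export
autoplot.null_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$densities,
                              cols = c("mean_accuracy", "mean_auc"),
                              names_to = "metric", values_to = "value")
  long$metric <- sub("mean_", "", long$metric)
  prop <- object$proposed
  names(prop)[names(prop) == "boot_mean"] <- "value"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "#7fbf7b", alpha = 0.5) +
    ggplot2::geom_vline(data = prop,
                        ggplot2::aes(xintercept = .data$value),
                        colour = "#d73027", linewidth = 0.9) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Bootstrap-mean performance", y = "Density",
                  title = "Random models vs proposed model (red line)") +
    ggplot2::theme_minimal()
}

#' Plot the merged feature-frequency ranking
#'
#' @param object A `feature_ranking` from [merge_correlated()].
#' @param top_n How many top-ranked features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, top_n = 20, ...) {
  d <- head(as_tibble(object), top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$merged_freq, y = .data$feature)) +
    ggplot2::geom_col(fill = "#2c6fa8") +
    ggplot2::geom_col(ggplot2::aes(x = .data$raw_freq), fill = "#9ecae1") +
    ggplot2::labs(x = "Frequency in final GA models (light: raw, dark: merged)",
                  y = NULL, title = "Correlation-merged feature ranking") +
    ggplot2::theme_minimal()
}
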