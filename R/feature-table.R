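#' Build a feature table
#'
#' A feature table is a tibble with one row per subject: a `subject_id`
#' column, a `label` column holding the diagnostic class, and one numeric
#' column per feature (binary clinical flags coded 0/1). Missing measurements
#' are `NA`. Optional per-feature modality tags and the standardization
#' record travel along as attributes.
#'
#' @param data A data frame with columns `subject_id`, `label`, and numeric
#'   feature columns.
#' @param modality Optional tibble with columns `feature`, `modality`
#'   tagging each feature (e.g. `"mri_volume"`, `"pet"`, `"fluid"`,
#'   `"clinical"`).
#' @return A `feature_tbl` (a tibble subclass).
#' @export
feature_table <- function(data, modality = NULL) {
  data <- as_tibble(data)
  if (!all(c("subject_id", "label") %in% names(data))) {
    abort("A feature table needs `subject_id` and `label` columns.")
  }
  if (anyDuplicated(data$subject_id)) {
    abort("`subject_id` values must be unique.")
  }
  if (anyNA(data$label)) {
    abort("Every subject must have a diagnostic label.")
  }
  feats <- setdiff(names(data), c("subject_id", "label"))
  not_num <- feats[!vapply(data[feats], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0("Feature columns must be numeric: ",
                 paste(not_num, collapse = ", ")))
  }
  data$subject_id <- as.character(data$subject_id)
  data$label <- as.character(data$label)
  new_feature_tbl(data, modality = modality)
}

new_feature_tbl <- function(data, modality = NULL, standardization = NULL,
                            dropped = NULL) {
  out <- as_tibble(data)
  class(out) <- unique(c("feature_tbl", class(out)))
  attr(out, "modality") <- modality
  attr(out, "standardization") <- standardization
  attr(out, "dropped") <- dropped
  out
}

# Carry feature-table attributes across a row/column subset.
rebuild_feature_tbl <- function(data, template, dropped = NULL) {
  feats <- setdiff(names(data), c("subject_id", "label"))
  mod <- attr(template, "modality")
  if (!is.null(mod)) mod <- mod[mod$feature %in% feats, , drop = FALSE]
  std <- attr(template, "standardization")
  if (!is.null(std)) std <- std[std$feature %in% feats, , drop = FALSE]
  new_feature_tbl(data, modality = mod, standardization = std,
                  dropped = dropped %||% attr(template, "dropped"))
}

#' Read / write feature tables
#'
#' The on-disk format is a plain CSV whose first column is the subject id
#' and second column the diagnostic label; every remaining column is a
#' feature. Empty cells or `NA` mark missing values. An optional companion
#' TSV maps features to modalities.
#'
#' @param path CSV path.
#' @param modality_path Optional TSV with columns `feature`, `modality`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, modality_path = NULL) {
  raw <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE)
  names(raw)[1:2] <- c("subject_id", "label")
  raw$subject_id <- as.character(raw$subject_id)
  raw$label <- as.character(raw$label)
  modality <- NULL
  if (!is.null(modality_path)) {
    modality <- readr::read_tsv(modality_path, show_col_types = FALSE)
  }
  feature_table(raw, modality = modality)
}

#' @rdname read_feature_table
#' @param data A feature table.
#' @export
write_feature_table <- function(data, path) {
  readr::write_csv(as_tibble(data), path, na = "")
  invisible(path)
}

#' Z-standardize every feature over the whole loaded population
#'
#' Each feature column x_j is replaced by (x_j - mu_j) / sigma_j with mu_j
#' and sigma_j the mean and sample standard deviation (n - 1 denominator)
#' over all non-missing values of all subjects currently in the table --
#' i.e. the whole study population, not a per-class or per-contrast subset.
#' Binary flags are variables like any other and are standardized
#' identically. The (mu_j, sigma_j) pairs are recorded in the
#' `standardization` attribute.
#'
#' @param data A feature table.
#' @return The standardized feature table; missing cells stay missing.
#' @export
z_standardize <- function(data) {
  feats <- feature_names(data)
  mu <- vapply(data[feats], function(x) mean(x, na.rm = TRUE), numeric(1))
  sigma <- vapply(data[feats], function(x) sd(x, na.rm = TRUE), numeric(1))
  nn <- vapply(data[feats], function(x) sum(!is.na(x)), integer(1))
  if (any(nn < 2)) {
    abort(paste0("Need at least 2 non-missing values to standardize: ",
                 paste(feats[nn < 2], collapse = ", ")))
  }
  degenerate <- feats[!is.na(sigma) & sigma == 0]
  if (length(degenerate) > 0) {
    abort(paste0("Zero-variance feature(s) cannot be z-standardized: ",
                 paste(degenerate, collapse = ", ")))
  }
  out <- data
  for (j in seq_along(feats)) {
    out[[feats[j]]] <- (data[[feats[j]]] - mu[j]) / sigma[j]
  }
  std <- tibble(feature = feats, mu = unname(mu), sigma = unname(sigma))
  res <- rebuild_feature_tbl(out, data)
  attr(res, "standardization") <- std
  res
}

#' Drop features with excessive missingness in either class
#'
#' Restricted to the two classes of the analysis spec, a feature is dropped
#' when its missing fraction strictly exceeds `spec$missing_threshold`
#' (default 20%) in either class; a feature missing for exactly the
#' threshold fraction is retained. The drop log (feature and per-class
#' missing fractions) is attached as the `dropped` attribute, retrievable
#' with [dropped_features()].
#'
#' @param data A feature table.
#' @param spec An [analysis_spec()].
#' @return The table restricted to the contrast's two classes with the
#'   surviving features.
#' @export
filter_missing <- function(data, spec) {
  data <- restrict_contrast(data, spec)
  feats <- feature_names(data)
  frac_by_class <- function(cls) {
    sub <- data[data$label == cls, feats, drop = FALSE]
    vapply(sub, function(x) mean(is.na(x)), numeric(1))
  }
  f_ctrl <- frac_by_class(spec$class_control)
  f_case <- frac_by_class(spec$class_case)
  drop <- f_ctrl > spec$missing_threshold | f_case > spec$missing_threshold
  log <- tibble(
    feature = feats[drop],
    frac_control = unname(f_ctrl[drop]),
    frac_case = unname(f_case[drop])
  )
  keep <- c("subject_id", "label", feats[!drop])
  rebuild_feature_tbl(data[, keep, drop = FALSE], data, dropped = log)
}

#' @rdname filter_missing
#' @export
dropped_features <- function(data) {
  attr(data, "dropped") %||% tibble(feature = character(),
                                    frac_control = numeric(),
                                    frac_case = numeric())
}

#' Complete-case subject subset for a feature set
#'
#' Subjects with a missing value on any of the listed features are removed;
#' subject order is preserved. This is the population every model fit and
#' IDI comparison uses.
#'
#' @param data A feature table.
#' @param features Character vector of feature names (may be empty, in which
#'   case the table is returned unchanged).
#' @return The subset table.
#' @export
complete_case_subset <- function(data, features) {
  assert_features_exist(data, features)
  if (length(features) == 0) return(data)
  keep <- complete.cases(data[, features, drop = FALSE])
  out <- data[keep, , drop = FALSE]
  classes <- unique(data$label)
  counts <- vapply(classes, function(cl) sum(out$label == cl), numeric(1))
  if (any(counts < 2)) {
    abort(paste0("Fewer than 2 complete-case subjects left in class '",
                 classes[which(counts < 2)[1]], "'."))
  }
  rebuild_feature_tbl(out, data)
}

#' @export
print.feature_tbl <- function(x, ...) {
  nf <- length(feature_names(x))
  cat("# A feature table: ", nrow(x), " subjects x ", nf, " features\n",
      sep = "")
  cat("# Classes: ",
      paste(sprintf("%s (%d)", names(table(x$label)), table(x$label)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(attr(x, "standardization"))) cat("# z-standardized\n")
  NextMethod()
}
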