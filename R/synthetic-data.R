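#' Configure a synthetic multimodal cohort
#'
#' Describes an ADNI-like case-control cohort: three diagnostic classes,
#' several hundred features organised in modality blocks (MRI volume /
#' thickness / surface, PET, fluid assays, binary clinical flags), a small
#' set of planted class-separating features with known standardized effect
#' sizes, highly correlated duplicate features, and per-modality
#' missing-completely-at-random rates. Defaults mirror the study scale:
#' 48 / 98 / 48 subjects per class and 650 features.
#'
#' @param n_per_class Named integer vector of class sizes.
#' @param n_features Total number of features.
#' @param planted Tibble with columns `feature` (global feature index),
#'   `contrast` (e.g. `"HC-AD"`; the shift is applied to the case class,
#'   the second name), and `delta` (standardized mean shift, sign
#'   included). The default plants five delta = 1.5 features for HC-AD and
#'   five delta = 1 features for each of HC-MCI and MCI-AD.
#' @param n_correlated_pairs Number of duplicate features generated as
#'   `rho * parent + sqrt(1 - rho^2) * noise`; the first duplicates shadow
#'   planted features (mimicking e.g. left/right-hemisphere homologues),
#'   the rest shadow noise features.
#' @param duplicate_rho Target Pearson correlation of each duplicate with
#'   its parent (must exceed 0.8 to engage frequency merging).
#' @param missing_rates Named per-modality MCAR probabilities.
#' @param binary_fraction Share of features that are binary clinical flags.
#' @param binary_prevalence Latent-normal threshold prevalence of the flags.
#' @param seed Integer seed; the emitted table is bit-reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(HC = 48, MCI = 98, AD = 48),
                          n_features = 650,
                          planted = NULL,
                          n_correlated_pairs = 20,
                          duplicate_rho = 0.9,
                          missing_rates = c(mri_volume = 0.05,
                                            mri_thickness = 0.05,
                                            mri_surface = 0.05,
                                            pet = 0.10, fluid = 0.15,
                                            clinical = 0.02),
                          binary_fraction = 0.10,
                          binary_prevalence = 0.3,
                          seed = 1L) {
  if (is.null(planted)) {
    planted <- tibble(
      feature = 1:15,
      contrast = rep(c("HC-AD", "HC-MCI", "MCI-AD"), each = 5),
      delta = rep(c(1.5, 1.0, 1.0), each = 5)
    )
    planted <- planted[planted$contrast %in%
                         planted_contrasts(names(n_per_class)), , drop = FALSE]
  }
  cfg <- structure(list(
    n_per_class = n_per_class, n_features = as.integer(n_features),
    planted = as_tibble(planted),
    n_correlated_pairs = as.integer(n_correlated_pairs),
    duplicate_rho = duplicate_rho, missing_rates = missing_rates,
    binary_fraction = binary_fraction,
    binary_prevalence = binary_prevalence, seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

planted_contrasts <- function(classes) {
  if (length(classes) < 2) return(character())
  pairs <- utils::combn(classes, 2)
  apply(pairs, 2, paste, collapse = "-")
}

validate_cohort_config <- function(cfg) {
  if (is.null(names(cfg$n_per_class)) || any(cfg$n_per_class < 1)) {
    abort("`n_per_class` must be a named vector of positive counts.")
  }
  if (!all(is.finite(cfg$planted$delta))) abort("Planted deltas must be finite.")
  if (cfg$duplicate_rho <= 0.8 || cfg$duplicate_rho >= 1) {
    warn("`duplicate_rho` outside (0.8, 1): duplicates will not engage merging.")
  }
  if (any(cfg$missing_rates < 0 | cfg$missing_rates > 0.5)) {
    abort("Missing rates must lie in [0, 0.5].")
  }
  bad <- cfg$planted$feature[cfg$planted$feature > cfg$n_features]
  if (length(bad) > 0) abort("Planted feature index beyond `n_features`.")
  invisible(cfg)
}

# Modality layout: clinical flags take `binary_fraction` of the features at
# the end of the table; the continuous remainder is split evenly over the
# five continuous modalities.
modality_layout <- function(cfg) {
  n_clin <- round(cfg$n_features * cfg$binary_fraction)
  n_cont <- cfg$n_features - n_clin
  cont_mods <- c("mri_volume", "mri_thickness", "mri_surface", "pet", "fluid")
  sizes <- diff(round(seq(0, n_cont, length.out = length(cont_mods) + 1)))
  modality <- c(rep(cont_mods, times = sizes), rep("clinical", n_clin))
  name <- paste0(modality, "_",
                 unlist(lapply(table(factor(modality, levels = unique(modality))),
                               function(k) sprintf("%03d", seq_len(k)))))
  tibble(feature = name, modality = modality)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Noise features are standard normal within every class; each planted
#' feature has its case-class mean shifted by `delta`, so its single-feature
#' population AUC is `pnorm(delta / sqrt(2))`. Duplicate features are
#' `rho * parent + sqrt(1 - rho^2) * noise`. Clinical flags are latent
#' normals thresholded at the configured prevalence. The MCAR mask is
#' applied per modality last.
#'
#' @param config A [cohort_config()].
#' @return A list with `table` (a [feature_table()]) and `truth`, the
#'   ground-truth record (planted features, duplicate map, config).
#' @export
generate_cohort <- function(config) {
  layout <- modality_layout(config)
  nf <- config$n_features
  n <- sum(config$n_per_class)
  labels <- rep(names(config$n_per_class), times = config$n_per_class)
  clin <- layout$modality == "clinical"
  planted <- config$planted
  if (any(clin[planted$feature])) {
    abort("Planted feature indices must fall on continuous features.")
  }

  withr::with_seed(config$seed, {
    z <- matrix(rnorm(n * nf), nrow = n, ncol = nf)
    for (i in seq_len(nrow(planted))) {
      case <- strsplit(planted$contrast[i], "-", fixed = TRUE)[[1]][2]
      if (!case %in% labels) abort(paste0("Unknown planted class: ", case))
      z[labels == case, planted$feature[i]] <-
        z[labels == case, planted$feature[i]] + planted$delta[i]
    }

    # duplicate pairs: planted parents first, then noise parents
    dup <- NULL
    if (config$n_correlated_pairs > 0) {
      cont_idx <- which(!clin)
      free <- setdiff(cont_idx, planted$feature)
      children <- sample(free, config$n_correlated_pairs)
      pool <- setdiff(free, children)
      n_sig <- min(nrow(planted), config$n_correlated_pairs)
      parents <- c(planted$feature[seq_len(n_sig)],
                   sample(pool, config$n_correlated_pairs - n_sig))
      if (any(parents %in% children)) {
        abort("Duplicate parent collides with a duplicate child.")
      }
      rho <- config$duplicate_rho
      for (i in seq_len(config$n_correlated_pairs)) {
        z[, children[i]] <- rho * z[, parents[i]] +
          sqrt(1 - rho^2) * z[, children[i]]
      }
      dup <- tibble(parent = layout$feature[parents],
                    child = layout$feature[children], rho = rho)
    }

    x <- z
    if (any(clin)) {
      thr <- qnorm(1 - config$binary_prevalence)
      x[, clin] <- as.numeric(z[, clin] > thr)
    }

    # per-modality MCAR mask
    for (mod in unique(layout$modality)) {
      rate <- if (mod %in% names(config$missing_rates)) {
        config$missing_rates[[mod]]
      } else 0
      if (rate <= 0) next
      cols <- which(layout$modality == mod)
      mask <- matrix(runif(n * length(cols)) < rate, nrow = n)
      x[, cols][mask] <- NA_real_
    }
  })

  colnames(x) <- layout$feature
  tbl <- feature_table(
    bind_cols(tibble(subject_id = sprintf("S%04d", seq_len(n)),
                     label = labels), as_tibble(x)),
    modality = layout
  )
  truth <- list(
    planted = mutate(planted, feature = layout$feature[planted$feature]),
    duplicates = dup %||% tibble(parent = character(), child = character(),
                                 rho = numeric()),
    config = config
  )
  list(table = tbl, truth = truth)
}

#' Overwrite features as correlated duplicates of existing parents
#'
#' Each `child` column is rebuilt as `rho * parent + sqrt(1 - rho^2) *
#' noise` (an exact copy when `rho = 1`), so the emitted pair attains the
#' target Pearson correlation in expectation. A child is missing wherever
#' its parent is missing, in addition to its own pre-existing missing
#' cells.
#'
#' @param data A feature table.
#' @param pairs Tibble with columns `parent`, `child`, `rho`.
#' @param seed Seed for the fresh noise draws.
#' @return The modified feature table.
#' @export
plant_correlates <- function(data, pairs, seed = 1L) {
  assert_features_exist(data, c(pairs$parent, pairs$child))
  if (any(pairs$rho <= 0.8)) {
    warn("Target rho <= 0.8: pair(s) will not trigger frequency merging.")
  }
  out <- data
  withr::with_seed(seed, {
    for (i in seq_len(nrow(pairs))) {
      p <- data[[pairs$parent[i]]]
      old_na <- is.na(out[[pairs$child[i]]])
      rho <- pairs$rho[i]
      child <- if (rho >= 1) p else {
        rho * p + sqrt(1 - rho^2) * rnorm(length(p))
      }
      child[old_na | is.na(p)] <- NA_real_
      out[[pairs$child[i]]] <- child
    }
  })
  rebuild_feature_tbl(out, data)
}

#' Write a synthetic cohort to disk
#'
#' Emits the standard input CSV, the feature-to-modality TSV, and a
#' ground-truth JSON.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "cohort.csv"),
    modality = file.path(dir, "modality.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_feature_table(cohort$table, paths["table"])
  readr::write_tsv(attr(cohort$table, "modality"), paths["modality"])
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  truth$config$planted <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
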