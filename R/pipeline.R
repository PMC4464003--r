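#' Configure an end-to-end pipeline run
#'
#' Binds an [analysis_spec()], a data source (either a [cohort_config()] to
#' simulate or an input CSV), the output directory, and the stage toggles.
#'
#' @param spec An [analysis_spec()].
#' @param outdir Output directory for stage artifacts and the manifest.
#' @param cohort Optional [cohort_config()]; when given, the `simulate`
#'   stage generates the input table.
#' @param input_csv,modality_tsv Optional paths to a prepared input table
#'   (used when `cohort` is `NULL`).
#' @param fs_fraction Fraction of the contrast's subjects (stratified by
#'   class, seeded) reserved as the feature-selection set; the remainder
#'   feeds the a-posteriori validation split. Roughly a third in the
#'   source study.
#' @param stages Stages to run, in order.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(spec, outdir, cohort = NULL, input_csv = NULL,
                            modality_tsv = NULL, fs_fraction = 1 / 3,
                            stages = c("simulate", "standardize", "filter",
                                       "search", "rank", "forward",
                                       "backward", "split", "bootstrap",
                                       "null")) {
  if (is.null(cohort) && is.null(input_csv)) {
    abort("Provide either a `cohort` config or an `input_csv`.")
  }
  structure(list(spec = spec, outdir = outdir, cohort = cohort,
                 input_csv = input_csv, modality_tsv = modality_tsv,
                 fs_fraction = fs_fraction, stages = stages),
            class = "pipeline_config")
}

#' Run the full panel-selection pipeline
#'
#' Executes the enabled stages in their canonical order -- simulate (or
#' load), standardize, filter, GA search, rank/merge, forward selection,
#' backward elimination, APIS split + calibration, bootstrap evaluation,
#' random-model null -- writing every intermediate artifact to the output
#' directory plus a manifest JSON recording the package version, seeds,
#' per-stage timings, key counts and file checksums. Rerunning with the
#' same configuration reproduces all artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  spec <- config$spec
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "paneldx",
                   version = as.character(utils::packageVersion("paneldx")),
                   rng_seed = spec$rng_seed,
                   contrast = paste(spec$class_control, spec$class_case,
                                    sep = "-"),
                   stages = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    value <- expr
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    list(value = value, elapsed = round(elapsed, 3))
  }
  record <- function(name, elapsed, files, counts = list()) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      stage = name, elapsed_s = elapsed,
      counts = counts,
      files = lapply(files, function(f) {
        list(path = basename(f), md5 = unname(tools::md5sum(f)))
      })
    )
  }
  path <- function(...) file.path(config$outdir, ...)
  on <- function(stage) stage %in% config$stages

  # -- simulate / load -------------------------------------------------
  if (on("simulate") && !is.null(config$cohort)) {
    st <- t_stage("simulate", {
      cohort <- generate_cohort(config$cohort)
      write_cohort(cohort, config$outdir)
      cohort
    })
    results$cohort <- st$value
    tbl <- st$value$table
    record("simulate", st$elapsed,
           path(c("cohort.csv", "modality.tsv", "ground_truth.json")),
           list(subjects = nrow(tbl), features = length(feature_names(tbl))))
  } else {
    tbl <- read_feature_table(config$input_csv, config$modality_tsv)
  }

  # -- standardize ------------------------------------------------------
  if (on("standardize")) {
    st <- t_stage("standardize", z_standardize(tbl))
    tbl <- st$value
    f_std <- path("standardized.csv")
    f_rec <- path("standardization.tsv")
    write_feature_table(tbl, f_std)
    readr::write_tsv(attr(tbl, "standardization"), f_rec)
    record("standardize", st$elapsed, c(f_std, f_rec),
           list(features = length(feature_names(tbl))))
  }
  results$standardized <- tbl

  # -- filter + feature-selection subset -------------------------------
  filtered <- NULL
  fs_tbl <- NULL
  if (on("filter")) {
    st <- t_stage("filter", filter_missing(tbl, spec))
    filtered <- st$value
    f_flt <- path("filtered.csv")
    f_drop <- path("dropped.tsv")
    write_feature_table(filtered, f_flt)
    readr::write_tsv(dropped_features(filtered), f_drop)
    # seeded stratified feature-selection subset
    ids <- filtered$subject_id
    fs_ids <- withr::with_seed(stage_seed(spec$rng_seed, "subset"), {
      unlist(lapply(split(ids, filtered$label), function(v) {
        sample(v, max(2, round(length(v) * config$fs_fraction)))
      }), use.names = FALSE)
    })
    fs_tbl <- filtered[filtered$subject_id %in% fs_ids, , drop = FALSE]
    fs_tbl <- rebuild_feature_tbl(fs_tbl, filtered)
    record("filter", st$elapsed, c(f_flt, f_drop),
           list(features_kept = length(feature_names(filtered)),
                features_dropped = nrow(dropped_features(filtered)),
                fs_subjects = nrow(fs_tbl)))
    results$filtered <- filtered
    results$fs_ids <- fs_tbl$subject_id
  }

  # -- GA search --------------------------------------------------------
  ga <- NULL
  if (on("search")) {
    st <- t_stage("search", ga_search(fs_tbl, spec))
    ga <- st$value
    f_chr <- path("chromosomes.tsv")
    f_frq <- path("frequencies.tsv")
    readr::write_tsv(mutate(ga$models, genes = vapply(
      .data$genes, paste, character(1), collapse = ";")), f_chr)
    readr::write_tsv(ga$frequencies, f_frq)
    record("search", st$elapsed, c(f_chr, f_frq),
           list(models = nrow(ga$models), failed = ga$n_failed))
    results$ga <- ga
  }

  # -- rank / merge -----------------------------------------------------
  ranking <- NULL
  if (on("rank")) {
    st <- t_stage("rank", merge_correlated(ga, fs_tbl, spec))
    ranking <- st$value
    f_rank <- path("ranking.tsv")
    f_log <- path("merge_log.tsv")
    readr::write_tsv(tidy(ranking), f_rank)
    readr::write_tsv(attr(ranking, "merge_log"), f_log)
    record("rank", st$elapsed, c(f_rank, f_log),
           list(retained = nrow(ranking),
                merged = nrow(attr(ranking, "merge_log"))))
    results$ranking <- ranking
  }

  # -- forward selection ------------------------------------------------
  fs_model <- NULL
  if (on("forward")) {
    st <- t_stage("forward", forward_select(ranking, fs_tbl, spec))
    fs_model <- st$value
    f_mod <- path("fs_model.json")
    f_aud <- path("fs_audit.tsv")
    write_model_json(fs_model, f_mod)
    readr::write_tsv(attr(fs_model, "audit"), f_aud)
    record("forward", st$elapsed, c(f_mod, f_aud),
           list(features = length(fs_model$features)))
    results$fs_model <- fs_model
  }

  # -- backward elimination --------------------------------------------
  final_model <- NULL
  if (on("backward")) {
    st <- t_stage("backward", backward_eliminate(fs_model, fs_tbl, spec))
    final_model <- st$value
    f_mod <- path("final_model.json")
    f_aud <- path("be_audit.tsv")
    write_model_json(final_model, f_mod)
    readr::write_tsv(attr(final_model, "audit"), f_aud)
    record("backward", st$elapsed, c(f_mod, f_aud),
           list(features = length(final_model$features)))
    results$final_model <- final_model
  }

  # -- APIS split + calibration ----------------------------------------
  split_plan <- NULL
  calibrated <- NULL
  if (on("split")) {
    st <- t_stage("split", {
      plan <- build_apis(tbl, final_model, results$fs_ids, spec)
      cal <- calibrate_model(tbl, final_model, plan, spec)
      list(plan = plan, calibrated = cal)
    })
    split_plan <- st$value$plan
    calibrated <- st$value$calibrated
    f_split <- path("split.json")
    f_cal <- path("calibrated_model.json")
    jsonlite::write_json(unclass(split_plan), f_split, auto_unbox = TRUE,
                         digits = NA)
    write_model_json(calibrated, f_cal)
    record("split", st$elapsed, c(f_split, f_cal),
           list(calibration = length(split_plan$calibration_ids),
                test = length(split_plan$test_ids)))
    results$split <- split_plan
    results$calibrated <- calibrated
  }

  # -- bootstrap evaluation (calibration) + blind test ------------------
  if (on("bootstrap")) {
    st <- t_stage("bootstrap", {
      cal_tbl <- tbl[tbl$subject_id %in% split_plan$calibration_ids, ,
                     drop = FALSE]
      cal_eval <- bootstrap_evaluate(calibrated, cal_tbl, spec)
      test_eval <- NULL
      if (length(split_plan$test_ids) > 0) {
        test_tbl <- tbl[tbl$subject_id %in% split_plan$test_ids, ,
                        drop = FALSE]
        test_tbl <- restrict_contrast(test_tbl, spec)
        scored <- predict_prob(calibrated, test_tbl)
        test_eval <- classification_metrics(scored, spec)
        attr(test_eval, "roc") <- roc_curve(scored, spec)
      }
      list(calibration = cal_eval, test = test_eval)
    })
    perf <- tidy(st$value$calibration)
    perf$cohort <- "calibration"
    if (!is.null(st$value$test)) {
      te <- st$value$test
      perf <- bind_rows(perf, tibble(
        metric = c("accuracy", "sensitivity", "specificity", "auc"),
        estimate = unlist(te[1, c("accuracy", "sensitivity",
                                  "specificity", "auc")]),
        boot_mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        cohort = "test"))
    }
    f_perf <- path("performance.csv")
    f_roc_c <- path("roc_calibration.csv")
    readr::write_csv(perf, f_perf)
    readr::write_csv(attr(st$value$calibration, "roc"), f_roc_c)
    files <- c(f_perf, f_roc_c)
    if (!is.null(st$value$test)) {
      f_roc_t <- path("roc_test.csv")
      readr::write_csv(attr(st$value$test, "roc"), f_roc_t)
      files <- c(files, f_roc_t)
    }
    record("bootstrap", st$elapsed, files,
           list(n_bootstrap = spec$n_bootstrap))
    results$evaluation <- st$value
  }

  # -- random-model null ------------------------------------------------
  if (on("null")) {
    st <- t_stage("null", {
      random_model_null(
        calibrated, filtered, spec,
        calibration_ids = split_plan$calibration_ids,
        feature_pool = feature_names(filtered),
        proposed_eval = results$evaluation$calibration
      )
    })
    f_den <- path("null_densities.csv")
    f_sum <- path("null_summary.json")
    readr::write_csv(st$value$densities, f_den)
    jsonlite::write_json(
      list(p_accuracy = st$value$p_accuracy, p_auc = st$value$p_auc,
           bands = st$value$bands, proposed = st$value$proposed),
      f_sum, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    record("null", st$elapsed, c(f_den, f_sum),
           list(n_random_models = nrow(st$value$densities)))
    results$null <- st$value
  }

  f_manifest <- path("manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  results$manifest_path <- f_manifest
  invisible(results)
}
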