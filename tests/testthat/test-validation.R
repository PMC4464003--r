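validation_fixture <- function(n = 230, seed = 71) {
  lab <- rep(c("HC", "AD"), length.out = n)
  withr::with_seed(seed, {
    feats <- list(sig = rnorm(n) + ifelse(lab == "AD", 1.5, 0),
                  extra = rnorm(n))
  })
  two_class_table(feats, labels = lab)
}

test_that("the APIS sample size solves the 4:1 proportion exactly", {
  tbl <- validation_fixture(230)
  spec <- default_spec()
  model <- fit_logistic(tbl, "sig", spec)
  fs_ids <- tbl$subject_id[1:130]
  plan <- build_apis(tbl, model, fs_ids, spec)
  expect_length(plan$apis_ids, 100)
  expect_equal(plan$m, 54)  # (4 * 100 - 130) / 5
  expect_length(plan$calibration_ids, 184)
  expect_length(plan$test_ids, 46)
  # true partition, reproducible
  expect_length(intersect(plan$calibration_ids, plan$test_ids), 0)
  expect_setequal(c(plan$calibration_ids, plan$test_ids),
                  union(fs_ids, plan$apis_ids))
  plan2 <- build_apis(tbl, model, fs_ids, spec)
  expect_identical(plan$calibration_ids, plan2$calibration_ids)
})

test_that("subjects missing a final-model feature are excluded from APIS", {
  tbl <- validation_fixture(60)
  tbl$sig[41:50] <- NA  # outside the FS set
  spec <- default_spec()
  model <- fit_logistic(tbl, "sig", spec)
  fs_ids <- tbl$subject_id[1:40]
  plan <- suppressWarnings(build_apis(tbl, model, fs_ids, spec))
  expect_setequal(plan$apis_ids, tbl$subject_id[51:60])
})

test_that("an unreachable ratio is clamped and an empty APIS degenerates", {
  tbl <- validation_fixture(40)
  spec <- default_spec()
  model <- fit_logistic(tbl, "sig", spec)
  # tiny APIS: target m exceeds the feasible range
  expect_warning(plan <- build_apis(tbl, model, tbl$subject_id[1:38], spec),
                 "clamped")
  expect_gte(length(plan$test_ids), 1)
  expect_warning(empty <- build_apis(tbl, model, tbl$subject_id, spec),
                 "empty")
  expect_length(empty$test_ids, 0)
  expect_identical(empty$calibration_ids, tbl$subject_id)
})

test_that("calibrating on the feature-selection set reproduces the original fit", {
  tbl <- validation_fixture()
  spec <- default_spec()
  model <- fit_logistic(tbl, "sig", spec)
  plan <- list(fs_ids = tbl$subject_id, apis_ids = character(),
               calibration_ids = tbl$subject_id, test_ids = character())
  cal <- calibrate_model(tbl, model, plan, spec)
  expect_equal(cal$coefficients, model$coefficients, tolerance = 1e-10)
  expect_length(attr(cal, "sign_flips"), 0)
})

test_that("coefficient sign flips after calibration are reported", {
  tbl <- validation_fixture()
  spec <- default_spec()
  model <- fit_logistic(tbl, "sig", spec)
  flipped <- model
  flipped$coefficients[["sig"]] <- -flipped$coefficients[["sig"]]
  plan <- list(calibration_ids = tbl$subject_id)
  expect_warning(cal <- calibrate_model(tbl, flipped, plan, spec),
                 "sign flip")
  expect_equal(attr(cal, "sign_flips"), "sig")
})

test_that("bootstrap evaluation is seed-reproducible with coherent intervals", {
  tbl <- validation_fixture()
  spec <- default_spec(n_bootstrap = 200)
  model <- fit_logistic(tbl, "sig", spec)
  e1 <- bootstrap_evaluate(model, tbl, spec)
  e2 <- bootstrap_evaluate(model, tbl, spec)
  expect_identical(tidy(e1), tidy(e2))
  expect_true(all(e1$ci_low <= e1$boot_mean + 1e-12))
  expect_true(all(e1$boot_mean <= e1$ci_high + 1e-12))
  expect_true(all(e1$estimate >= 0 & e1$estimate <= 1))
  # bootstrap means sit near the point metrics on a decent sample
  expect_true(all(abs(e1$boot_mean - e1$estimate) < 0.05))
  roc <- attr(e1, "roc")
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("a perfectly separated model has zero-width intervals", {
  lab <- rep(c("HC", "AD"), each = 20)
  tbl <- two_class_table(list(s = ifelse(lab == "AD", 10, -10)), labels = lab)
  spec <- default_spec(n_bootstrap = 50)
  model <- suppressWarnings(fit_logistic(tbl, "s", spec))
  ev <- bootstrap_evaluate(model, tbl, spec)
  acc <- ev[ev$metric == "accuracy", ]
  expect_equal(unname(acc$ci_low), unname(acc$ci_high))
  expect_equal(unname(acc$estimate), 1)
})

test_that("the random-model null separates a real model from chance", {
  n <- 200
  lab <- rep(c("HC", "AD"), each = n / 2)
  withr::with_seed(81, {
    feats <- c(list(sig = rnorm(n) + ifelse(lab == "AD", 2, 0)),
               stats::setNames(replicate(20, rnorm(n), simplify = FALSE),
                               sprintf("n%02d", 1:20)))
  })
  tbl <- two_class_table(feats, labels = lab)
  spec <- default_spec(n_bootstrap = 50, n_random_models = 40)
  model <- fit_logistic(tbl, "sig", spec)
  null <- random_model_null(model, tbl, spec,
                            calibration_ids = tbl$subject_id,
                            feature_pool = sprintf("n%02d", 1:20))
  expect_equal(nrow(null$densities), 40)
  expect_equal(null$p_accuracy, 0)
  expect_equal(null$p_auc, 0)
  expect_true(all(null$bands$q025 <= null$bands$q975))
  null2 <- random_model_null(model, tbl, spec,
                             calibration_ids = tbl$subject_id,
                             feature_pool = sprintf("n%02d", 1:20))
  expect_identical(null$densities, null2$densities)
})
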