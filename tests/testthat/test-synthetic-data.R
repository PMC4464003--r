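test_that("generated cohorts have the configured composition and reproduce bit-for-bit", {
  cfg <- cohort_config(n_per_class = c(A = 40, B = 40), n_features = 50,
                       planted = data.frame(feature = 1, contrast = "A-B",
                                            delta = 1),
                       n_correlated_pairs = 4, seed = 5)
  c1 <- generate_cohort(cfg)
  expect_equal(nrow(c1$table), 80)
  expect_equal(as.vector(table(c1$table$label)[c("A", "B")]), c(40L, 40L))
  expect_equal(length(setdiff(names(c1$table), c("subject_id", "label"))), 50)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$table, c2$table)
  expect_true(all(c1$truth$planted$feature %in% names(c1$table)))
})

test_that("a planted shift delta yields the binormal AUC Phi(delta / sqrt(2))", {
  cfg <- cohort_config(n_per_class = c(A = 200, B = 200), n_features = 10,
                       planted = data.frame(feature = 1, contrast = "A-B",
                                            delta = 1.5),
                       n_correlated_pairs = 0, missing_rates = c(),
                       binary_fraction = 0, seed = 21)
  coh <- generate_cohort(cfg)
  f1 <- coh$truth$planted$feature[1]
  y <- as.numeric(coh$table$label == "B")
  expect_lt(abs(auc_vec(coh$table[[f1]], y) - pnorm(1.5 / sqrt(2))), 0.04)
  # and unplanted features stay near chance on average
  noise <- setdiff(names(coh$table), c("subject_id", "label", f1))
  dev_from_chance <- vapply(noise, function(f)
    abs(auc_vec(coh$table[[f]], y) - 0.5), numeric(1))
  expect_lt(mean(dev_from_chance), 0.05)
})

test_that("correlated duplicates reach their target correlation", {
  cfg <- cohort_config(n_per_class = c(A = 200, B = 200), n_features = 40,
                       planted = data.frame(feature = 1, contrast = "A-B",
                                            delta = 1),
                       n_correlated_pairs = 5, duplicate_rho = 0.9,
                       missing_rates = c(), binary_fraction = 0, seed = 8)
  coh <- generate_cohort(cfg)
  for (i in seq_len(nrow(coh$truth$duplicates))) {
    r <- cor(coh$table[[coh$truth$duplicates$parent[i]]],
             coh$table[[coh$truth$duplicates$child[i]]])
    expect_gt(r, 0.85)
    expect_lt(r, 0.95)
  }
})

test_that("plant_correlates handles exact copies, missing parents, and low targets", {
  tbl <- two_class_table(list(p = c(1, 2, NA, 4, 5, 6, 7, 8),
                              q = c(9, 8, 7, 6, NA, 4, 3, 2)))
  exact <- plant_correlates(tbl, data.frame(parent = "p", child = "q",
                                            rho = 1))
  expect_identical(exact$q[c(1, 2, 4)], tbl$p[c(1, 2, 4)])
  # child missing where the parent is missing, plus its own old gaps
  expect_true(is.na(exact$q[3]) && is.na(exact$q[5]))
  expect_warning(plant_correlates(tbl, data.frame(parent = "p", child = "q",
                                                  rho = 0.5)),
                 "merging")
})

test_that("per-modality missing rates match their binomial expectation", {
  cfg <- cohort_config(n_per_class = c(A = 150, B = 150), n_features = 200,
                       planted = data.frame(feature = 1, contrast = "A-B",
                                            delta = 1),
                       n_correlated_pairs = 0, seed = 13)
  coh <- generate_cohort(cfg)
  layout <- attr(coh$table, "modality")
  for (mod in unique(layout$modality)) {
    rate <- cfg$missing_rates[[mod]]
    cols <- layout$feature[layout$modality == mod]
    n_cells <- 300 * length(cols)
    emp <- mean(is.na(as.matrix(coh$table[, cols])))
    se <- sqrt(rate * (1 - rate) / n_cells)
    expect_lt(abs(emp - rate), 3 * se + 1e-12)
  }
})

test_that("logistic fits on the generating features recover the planted effects", {
  # independent unit-variance features shifted by delta have true logistic
  # coefficients equal to delta
  cfg <- cohort_config(n_per_class = c(A = 1000, B = 1000), n_features = 6,
                       planted = data.frame(feature = 1:3, contrast = "A-B",
                                            delta = c(1, 0.8, 1.2)),
                       n_correlated_pairs = 0, missing_rates = c(),
                       binary_fraction = 0, seed = 31)
  coh <- generate_cohort(cfg)
  spec <- analysis_spec("A", "B", rng_seed = 1)
  fit <- fit_logistic(coh$table, coh$truth$planted$feature, spec)
  bias <- abs(fit$coefficients - coh$truth$planted$delta) /
    coh$truth$planted$delta
  expect_true(all(bias < 0.15))
})

test_that("planted indices must fall on continuous features", {
  expect_error(generate_cohort(
    cohort_config(n_per_class = c(A = 20, B = 20), n_features = 20,
                  planted = data.frame(feature = 20, contrast = "A-B",
                                       delta = 1),
                  binary_fraction = 0.2, n_correlated_pairs = 0, seed = 1)),
    "continuous")
})
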