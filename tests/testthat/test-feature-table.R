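test_that("z-standardization matches direct arithmetic and records (mu, sigma)", {
  tbl <- two_class_table(list(a = c(1, 2, 3, 6), b = c(5, 5, 7, 7)))
  z <- z_standardize(tbl)
  # sample SD (n - 1) of [1, 2, 3, 6] is 2.1602
  expect_equal(z$a, c(-0.9258, -0.4629, 0, 1.3887), tolerance = 1e-4)
  expect_equal(z$a[3], 0)  # cell equal to its column mean
  rec <- attr(z, "standardization")
  expect_equal(rec$mu[rec$feature == "a"], 3)
  expect_equal(rec$sigma[rec$feature == "a"], sd(c(1, 2, 3, 6)))
  # a cell one recorded SD above the mean standardizes to 1
  expect_equal((rec$mu[1] + rec$sigma[1] - rec$mu[1]) / rec$sigma[1], 1)
  # standardized columns have mean ~0 and sample SD ~1
  expect_lt(abs(mean(z$b)), 1e-9)
  expect_lt(abs(sd(z$b) - 1), 1e-9)
})

test_that("z-standardization is idempotent and keeps missing cells missing", {
  tbl <- two_class_table(list(a = c(1, NA, 3, 6, 2, NA, 0, 4)))
  z1 <- z_standardize(tbl)
  z2 <- z_standardize(z1)
  expect_equal(z2$a, z1$a, tolerance = 1e-9)
  expect_identical(is.na(z1$a), is.na(tbl$a))
})

test_that("zero-variance columns abort with the column named", {
  tbl <- two_class_table(list(good = rnorm(8), flat = rep(2, 8)))
  expect_error(z_standardize(tbl), "flat")
})

test_that("binary flags are standardized like any other variable", {
  tbl <- two_class_table(list(flag = c(0, 0, 1, 1, 0, 1, 0, 1)))
  z <- z_standardize(tbl)
  expect_lt(abs(mean(z$flag)), 1e-9)
  expect_false(any(z$flag %in% c(0, 1)))
})

test_that("missingness filter drops strictly above the per-class threshold", {
  spec <- default_spec()
  n <- 20  # 10 per class
  mk <- function(n_miss_hc, n_miss_ad) {
    x <- rnorm(n)
    x[seq_len(n_miss_hc)] <- NA            # HC rows are 1..10
    if (n_miss_ad > 0) x[10 + seq_len(n_miss_ad)] <- NA
    x
  }
  tbl <- two_class_table(list(
    over = mk(3, 0),      # 30% in HC -> dropped
    at = mk(2, 2),        # exactly 20% in both -> retained
    full = rnorm(n),      # fully observed -> never dropped
    case_over = mk(0, 4), # 40% in AD -> dropped
    under = mk(1, 1),
    both_under = mk(2, 0)
  ))
  out <- filter_missing(tbl, spec)
  kept <- setdiff(names(out), c("subject_id", "label"))
  expect_setequal(kept, c("at", "full", "under", "both_under"))
  log <- dropped_features(out)
  expect_setequal(log$feature, c("over", "case_over"))
  expect_equal(log$frac_control[log$feature == "over"], 0.3)
})

test_that("dropping is monotone in the threshold", {
  spec_loose <- default_spec()
  spec_tight <- analysis_spec("HC", "AD", missing_threshold = 0.05,
                              rng_seed = 7)
  withr::with_seed(3, {
    x <- replicate(10, {
      v <- rnorm(40)
      v[sample(40, sample(0:10, 1))] <- NA
      v
    })
  })
  colnames(x) <- paste0("f", 1:10)
  tbl <- two_class_table(as.list(as.data.frame(x)))
  d_loose <- dropped_features(filter_missing(tbl, spec_loose))$feature
  d_tight <- dropped_features(filter_missing(tbl, spec_tight))$feature
  expect_true(all(d_loose %in% d_tight))
})

test_that("complete-case subsetting keeps exactly the fully observed subjects", {
  a <- c(1, NA, 3, 4, 5, 6, 7, 8)
  b <- c(1, 2, NA, 4, 5, 6, 7, 8)
  tbl <- two_class_table(list(a = a, b = b))
  expect_identical(complete_case_subset(tbl, character())$subject_id,
                   tbl$subject_id)
  expect_identical(complete_case_subset(tbl, "a")$subject_id,
                   tbl$subject_id[-2])
  both <- complete_case_subset(tbl, c("a", "b"))
  expect_identical(both$subject_id, tbl$subject_id[-c(2, 3)])
  # union subset is contained in each single-feature subset
  expect_true(all(both$subject_id %in% complete_case_subset(tbl, "a")$subject_id))
  expect_true(all(both$subject_id %in% complete_case_subset(tbl, "b")$subject_id))
})

test_that("complete-case subsetting errors when a class collapses", {
  a <- c(NA, NA, NA, 1, 1, 1, 2, 3)  # removes 3 of 4 HC
  tbl <- two_class_table(list(a = a))
  expect_error(complete_case_subset(tbl, "a"), "Fewer than 2")
})

test_that("feature tables survive a CSV round trip", {
  tbl <- two_class_table(list(a = c(1.5, NA, 3, 6, 2, 4, 0, 4), b = rnorm(8)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("feature table validation rejects malformed input", {
  expect_error(feature_table(data.frame(subject_id = c("a", "a"),
                                        label = c("x", "y"), f = 1:2)),
               "unique")
  expect_error(feature_table(data.frame(subject_id = c("a", "b"),
                                        label = c("x", NA), f = 1:2)),
               "label")
  expect_error(feature_table(data.frame(subject_id = c("a", "b"),
                                        label = c("x", "y"),
                                        f = c("p", "q"))),
               "numeric")
})
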