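# Fixture with exact pairwise correlations built from orthonormal columns:
# cor(f1, f2) = cor(f2, f3) = 0.9, cor(f1, f3) = 0.62.
chain_table <- function(n = 50) {
  u <- orthonormal_columns(n, 3, seed = 6)
  f2 <- u[, 1]
  f1 <- 0.9 * u[, 1] + sqrt(1 - 0.81) * u[, 2]
  f3 <- 0.9 * u[, 1] - sqrt(1 - 0.81) * u[, 2]
  two_class_table(list(f1 = f1, f2 = f2, f3 = f3,
                       other = u[, 3]),
                  labels = rep(c("HC", "AD"), length.out = n))
}

test_that("a correlated lower-frequency feature is absorbed with its frequency", {
  tbl <- chain_table()
  freqs <- tibble::tibble(feature = c("f1", "f2"), count = c(30L, 10L))
  rk <- merge_correlated(freqs, tbl, default_spec())
  expect_equal(rk$feature, "f1")
  expect_equal(rk$merged_freq, 40L)
  expect_equal(attr(rk, "merge_log")$discarded, "f2")
  expect_equal(attr(rk, "merge_log")$rho, 0.9, tolerance = 1e-10)
})

test_that("correlations at or below the threshold leave both features ranked", {
  tbl <- chain_table()
  freqs <- tibble::tibble(feature = c("f1", "f3"), count = c(30L, 10L))
  rk <- merge_correlated(freqs, tbl, default_spec())  # cor = 0.62
  expect_setequal(rk$feature, c("f1", "f3"))
  expect_equal(rk$merged_freq, rk$raw_freq)
})

test_that("the greedy pass follows raw-frequency order through chains", {
  tbl <- chain_table()
  freqs <- tibble::tibble(feature = c("f1", "f2", "f3"),
                          count = c(30L, 20L, 10L))
  rk <- merge_correlated(freqs, tbl, default_spec())
  # f1 absorbs f2 (rho 0.9); f3's only qualifying partner is already gone
  expect_setequal(rk$feature, c("f1", "f3"))
  expect_equal(rk$merged_freq[rk$feature == "f1"], 50L)
  expect_equal(rk$merged_freq[rk$feature == "f3"], 10L)
  # conservation
  expect_equal(sum(rk$merged_freq), sum(freqs$count))
})

test_that("pairs with fewer than 3 complete observations are skipped with a warning", {
  tbl <- chain_table(n = 8)
  tbl$f2[1:6] <- NA
  freqs <- tibble::tibble(feature = c("f1", "f2"), count = c(5L, 3L))
  expect_warning(rk <- merge_correlated(freqs, tbl, default_spec()),
                 "complete")
  expect_setequal(rk$feature, c("f1", "f2"))
})

selection_fixture <- function(n_per_class = 150, seed = 61) {
  n <- 2 * n_per_class
  lab <- rep(c("HC", "AD"), each = n_per_class)
  withr::with_seed(seed, {
    shift <- ifelse(lab == "AD", 1.5, 0)
    feats <- list(sig1 = rnorm(n) + shift, sig2 = rnorm(n) + shift)
    for (i in 1:8) feats[[sprintf("noise%d", i)]] <- rnorm(n)
  })
  two_class_table(feats, labels = lab)
}

test_that("forward selection includes the planted features and skips noise", {
  tbl <- selection_fixture()
  spec <- default_spec()
  ranking <- tibble::tibble(
    rank = 1:10,
    feature = c("noise1", "sig1", "noise2", "sig2", paste0("noise", 3:8)),
    raw_freq = 20:11, merged_freq = 20:11, mean_fitness = 0.5,
    absorbed = replicate(10, character(), simplify = FALSE))
  class(ranking) <- c("feature_ranking", class(ranking))
  model <- forward_select(ranking, tbl, spec)
  expect_setequal(model$features, c("sig1", "sig2"))
  audit <- attr(model, "audit")
  expect_equal(nrow(audit), 10)
  expect_setequal(audit$decision[audit$candidate %in% c("sig1", "sig2")],
                  "included")
  # deterministic under the same spec seed
  model2 <- forward_select(ranking, tbl, spec)
  expect_identical(model$features, model2$features)
})

test_that("a redundant near-duplicate of an included feature usually fails the gate", {
  # given the parent, a rho = 0.98 copy carries no class information; the
  # IDI gate should reject it at close to its nominal error rate
  skips <- vapply(1:12, function(r) {
    n <- 300
    lab <- rep(c("HC", "AD"), each = n / 2)
    withr::with_seed(600 + r, {
      sig1 <- rnorm(n) + ifelse(lab == "AD", 1.5, 0)
      dup <- 0.98 * sig1 + sqrt(1 - 0.98^2) * rnorm(n)
    })
    tbl <- two_class_table(list(sig1 = sig1, dup = dup), labels = lab)
    spec <- analysis_spec("HC", "AD", k_folds = 3, rng_seed = 700 + r)
    res <- paneldx:::idi_compare(tbl, "sig1", "dup", spec)
    !(res$idi > 0 && res$p < spec$idi_p)
  }, logical(1))
  expect_gte(sum(skips), 10)
})

test_that("an empty ranking is rejected and a futile one falls back to the intercept", {
  tbl <- selection_fixture()
  spec <- default_spec()
  empty <- tibble::tibble(rank = integer(), feature = character(),
                          raw_freq = integer(), merged_freq = integer(),
                          mean_fitness = numeric(),
                          absorbed = list())
  class(empty) <- c("feature_ranking", class(empty))
  expect_error(forward_select(empty, tbl, spec), "Empty ranking")
  noise_only <- tibble::tibble(
    rank = 1L, feature = "noise1", raw_freq = 1L, merged_freq = 1L,
    mean_fitness = 0.5, absorbed = list(character()))
  class(noise_only) <- c("feature_ranking", class(noise_only))
  expect_warning(model <- forward_select(noise_only, tbl, spec),
                 "intercept-only")
  expect_length(model$features, 0)
})

test_that("backward elimination removes appended noise but keeps real signal", {
  tbl <- selection_fixture()
  spec <- default_spec()
  start <- fit_logistic(tbl, c("sig1", "sig2", "noise1"), spec)
  reduced <- backward_eliminate(start, tbl, spec)
  expect_setequal(reduced$features, c("sig1", "sig2"))
  audit <- attr(reduced, "audit")
  expect_equal(audit$decision[audit$feature == "noise1" &
                                audit$cycle == 1], "removed")
  # a model whose features all pass is returned unchanged
  again <- backward_eliminate(reduced, tbl, spec)
  expect_setequal(again$features, reduced$features)
  expect_lte(length(again$features), length(start$features))
})

test_that("a single non-significant feature is eliminated to the intercept", {
  tbl <- selection_fixture()
  spec <- default_spec()
  start <- fit_logistic(tbl, "noise2", spec)
  reduced <- backward_eliminate(start, tbl, spec)
  expect_length(reduced$features, 0)
})
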