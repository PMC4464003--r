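# Shared fixtures and independent oracles for the test suite.

# Brute-force AUC: all case/control pairs, ties count one half.
brute_auc <- function(probs, y) {
  cases <- probs[y == 1]
  ctrls <- probs[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# Trapezoidal area under an ordered (fpr, tpr) polyline.
trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Small two-class table with named feature columns given as a list of
# numeric vectors (all the same length, split half control / half case).
two_class_table <- function(features, labels = NULL) {
  n <- length(features[[1]])
  if (is.null(labels)) labels <- rep(c("HC", "AD"), each = n / 2)
  df <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                   label = labels, check.names = FALSE)
  for (nm in names(features)) df[[nm]] <- features[[nm]]
  feature_table(df)
}

# Columns with exact sample correlations via orthonormalised noise:
# returns a matrix whose columns are centred, unit-norm, and pairwise
# orthogonal, for constructing fixtures with known correlation structure.
orthonormal_columns <- function(n, k, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * k), n, k)
    m <- scale(m, center = TRUE, scale = FALSE)
    q <- qr.Q(qr(m))
    q <- scale(q, center = TRUE, scale = FALSE)
    sweep(q, 2, sqrt(colSums(q^2)), "/")
  })
}

default_spec <- function(...) {
  analysis_spec("HC", "AD", k_folds = 3, rng_seed = 7, ...)
}
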