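# Internal helpers shared across modules.

# Deterministic stratified fold assignment: within each class, subjects are
# shuffled and dealt round-robin so fold sizes differ by at most one per class.
make_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Stage-tagged seed stream derived from one master seed; keeps every stage's
# randomness independent of whether other stages ran. Kept < 2^31.
stage_seed <- function(seed, tag) {
  offsets <- c(
    simulate = 101L, standardize = 211L, filter = 307L, subset = 113L,
    search = 401L,
    rank = 503L, forward = 601L, backward = 701L, split = 809L,
    calibrate = 907L, bootstrap = 1009L, null = 1103L
  )
  off <- offsets[[tag]]
  (as.integer(seed) %% 2000000000L) + off
}

# All feature columns of a feature table (everything but id + label).
feature_names <- function(data) {
  setdiff(names(data), c("subject_id", "label"))
}

assert_features_exist <- function(data, features) {
  missing <- setdiff(features, feature_names(data))
  if (length(missing) > 0) {
    abort(paste0("Unknown feature(s): ", paste(missing, collapse = ", ")))
  }
}

# Restrict a table to the two classes of an analysis spec, preserving order.
restrict_contrast <- function(data, spec) {
  keep <- data$label %in% c(spec$class_control, spec$class_case)
  out <- data[keep, , drop = FALSE]
  counts <- table(factor(out$label, levels = c(spec$class_control, spec$class_case)))
  if (any(counts == 0)) {
    abort(paste0("Class '", names(counts)[counts == 0][1],
                 "' has no subjects in the table."))
  }
  out
}

# 0/1 outcome coding: case class = 1.
outcome_vector <- function(labels, spec) {
  as.numeric(labels == spec$class_case)
}
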