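#' Build a labeled feature set
#'
#' A feature set is the basic container of the package: one embedding matrix
#' (one backbone layer) together with an integer class label per sample. It
#' is represented as a plain tibble with columns `sample_id`, `label`,
#' optionally `class_name`, and the embedding dimensions `f1..fn`, so it can
#' be filtered, joined and plotted with ordinary tidyverse verbs.
#'
#' Labels are 0-based contiguous integers `0..C-1`; `class_name`, when given,
#' carries the original string label of each sample.
#'
#' @param features Numeric matrix, samples in rows, embedding dimensions in
#'   columns. All values must be finite.
#' @param labels Integer vector of class indices in `0..C-1`, one per row of
#'   `features`. Every class index in the range must occur at least once.
#' @param class_names Optional character vector of length `C` giving the
#'   display name of each class.
#' @param sample_ids Optional character vector of stable sample identifiers;
#'   defaults to `s1..sM`.
#' @return A validated feature-set tibble.
#' @examples
#' fs <- feature_set(matrix(rnorm(12), 4, 3), c(0L, 0L, 1L, 1L))
#' feature_matrix(fs)
#' @export
feature_set <- function(features, labels, class_names = NULL, sample_ids = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  m <- nrow(features)
  n <- ncol(features)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(m))
  df <- tibble(sample_id = as.character(sample_ids), label = as.integer(labels))
  if (!is.null(class_names)) {
    df$class_name <- as.character(class_names)[df$label + 1L]
  }
  feats <- as_tibble(features, .name_repair = "minimal")
  names(feats) <- paste0("f", seq_len(n))
  df <- dplyr::bind_cols(df, feats)
  validate_feature_set(df)
}

#' Coerce a data frame to a feature set
#'
#' Accepts any data frame with `sample_id`, `label` and `f1..fn` columns
#' (the on-disk TSV dialect) and validates it.
#'
#' @param x A data frame.
#' @return A validated feature-set tibble.
#' @export
as_feature_set <- function(x) {
  validate_feature_set(as_tibble(x))
}

#' Validate the invariants of a feature set
#'
#' Checks, and reports by name, every structural rule a feature set must
#' satisfy: required columns, one label per row, finite feature values, and
#' 0-based contiguous class labels with every class present.
#'
#' @param x A data frame to validate.
#' @return `x`, invisibly coerced to a tibble, if valid; otherwise a
#'   validation error naming the violated rule.
#' @export
validate_feature_set <- function(x) {
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort_validation("invariant 'sample_id column present' violated")
  }
  if (!"label" %in% names(x)) {
    abort_validation("invariant 'label column present' violated")
  }
  cols <- feature_cols(x)
  if (length(cols) == 0) {
    abort_validation("invariant 'feature columns f1..fn present' violated")
  }
  fm <- as.matrix(x[, cols, drop = FALSE])
  if (!is.numeric(fm) || anyNA(fm) || any(!is.finite(fm))) {
    abort_validation("invariant 'all feature values finite' violated")
  }
  lab <- x$label
  if (anyNA(lab) || any(lab != floor(lab))) {
    abort_validation("invariant 'labels are integers' violated")
  }
  lab <- as.integer(lab)
  if (length(lab) != nrow(fm)) {
    abort_validation("invariant 'row count of features equals length of labels' violated")
  }
  u <- sort(unique(lab))
  if (length(u) == 0 || u[1] != 0L || !identical(u, seq(0L, max(lab)))) {
    abort_validation(
      "invariant 'class labels are 0-based contiguous and every class appears' violated")
  }
  x$label <- lab
  x
}

#' Number of classes in a feature set
#' @param x A feature-set tibble.
#' @return Integer count of distinct classes.
#' @export
n_classes <- function(x) {
  length(unique(x$label))
}

#' Embedding dimension of a feature set
#' @param x A feature-set tibble.
#' @return Integer number of feature columns.
#' @export
feature_dim <- function(x) {
  length(feature_cols(x))
}
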