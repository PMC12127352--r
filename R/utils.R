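# Internal helpers shared across modules. Errors are classed so callers and
# tests can distinguish user/validation errors from file-format errors.

abort_validation <- function(msg, ...) {
  abort(msg, class = "fascal_validation_error", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "fascal_format_error", ...)
}

#' Names of the feature columns of a feature set
#'
#' Feature sets are tibbles whose embedding dimensions live in columns
#' `f1`, `f2`, ..., `fn`. Returns the names in dimension order.
#'
#' @param x A data frame.
#' @return Character vector of feature column names, ordered by index.
#' @export
feature_cols <- function(x) {
  nm <- grep("^f[0-9]+$", names(x), value = TRUE)
  nm[order(as.integer(sub("^f", "", nm)))]
}

#' Extract the feature matrix of a feature set
#'
#' @param x A feature-set tibble (see [feature_set()]).
#' @return A numeric matrix, samples in rows, dimensions in columns.
#' @export
feature_matrix <- function(x) {
  cols <- feature_cols(x)
  if (length(cols) == 0) {
    abort_validation("feature set has no feature columns (expected f1..fn)")
  }
  m <- as.matrix(x[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Round a double vector/matrix to the nearest IEEE float32 value (storage
# precision of the bank format); statistics always run on the doubles.
as_float32 <- function(x) {
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 what = "numeric", n = length(x), size = 4L)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

# Deterministic derivation of per-run RNG substreams from one integer seed.
# Documented splitting rule: seed and run index are mixed by a fixed odd
# multiplier, reduced modulo 2^31 - 1 so the result is a valid integer seed.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 69069 + as.double(index) * 2654435761) %% 2147483647
  as.integer(s)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
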