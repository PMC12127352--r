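# Feature Adaptation Score (FAS): a training-free, per-layer statistic that
# predicts how well a layer's embeddings will support nearest-prototype
# few-shot classification. It combines the between/within-class variance
# ratio (a Fisher-style discriminant ratio) with the mean inter-centroid
# distance scaled by the layer dimension, so layers of different width are
# comparable:
#
#   FAS_l = sigma2_between / sigma2_within + Dbar / sqrt(n)
#
# The floor on sigma2_within avoids infinities on collapsed features.
FAS_EPS <- 1e-12

#' Per-class and global mean feature vectors
#'
#' @param fs A feature-set tibble.
#' @return A tibble with one row per class: `label`, `n` (class size) and
#'   the mean feature columns. The global mean (mean over all samples, i.e.
#'   the class means weighted by class size) is attached as attribute
#'   `global_mean`.
#' @examples
#' fs <- feature_set(matrix(c(-1, 1, 1, 3)), c(0L, 0L, 1L, 1L))
#' class_means(fs)
#' @export
class_means <- function(fs) {
  fs <- validate_feature_set(fs)
  m <- feature_matrix(fs)
  lab <- fs$label
  cm <- rowsum(m, lab) / as.vector(table(lab))
  out <- dplyr::bind_cols(
    tibble(label = sort(unique(lab)), n = as.integer(table(lab))),
    as_tibble(cm, .name_repair = "minimal")
  )
  attr(out, "global_mean") <- colMeans(m)
  out
}

cm_matrix <- function(cm) {
  as.matrix(cm[, feature_cols(cm), drop = FALSE])
}

#' Within-class variance of a feature set
#'
#' Mean squared Euclidean distance of every sample to its class mean,
#' averaged over all M samples (classes may be unbalanced; balanced input
#' reduces to the usual N*K normalization).
#'
#' @param fs A feature-set tibble.
#' @param cm Optional precomputed [class_means()] of `fs`.
#' @return Non-negative scalar.
#' @export
within_class_variance <- function(fs, cm = NULL) {
  fs <- validate_feature_set(fs)
  if (is.null(cm)) cm <- class_means(fs)
  m <- feature_matrix(fs)
  mu <- cm_matrix(cm)[match(fs$label, cm$label), , drop = FALSE]
  sum((m - mu)^2) / nrow(m)
}

#' Between-class variance of a set of class means
#'
#' Mean squared Euclidean distance of the class means to the global mean,
#' averaged over the N classes (each class counted once).
#'
#' @param cm A [class_means()] tibble.
#' @return Non-negative scalar.
#' @export
between_class_variance <- function(cm) {
  mu <- cm_matrix(cm)
  if (nrow(mu) < 2) {
    abort_validation("between_class_variance requires at least 2 classes")
  }
  g <- attr(cm, "global_mean")
  if (is.null(g)) g <- colSums(mu * cm$n) / sum(cm$n)
  mean(rowSums(sweep(mu, 2, g)^2))
}

#' Mean between-class distance
#'
#' Average *unsquared* Euclidean distance over all unordered pairs of class
#' means, `2/(N(N-1)) * sum_{i<j} ||mu_i - mu_j||`. Set `squared = TRUE` for
#' the squared-distance variant.
#'
#' @param cm A [class_means()] tibble.
#' @param squared Use squared distances instead (default `FALSE`).
#' @return Non-negative scalar; 0 iff all class means coincide.
#' @export
mean_between_class_distance <- function(cm, squared = FALSE) {
  mu <- cm_matrix(cm)
  n <- nrow(mu)
  if (n < 2) {
    abort_validation("mean_between_class_distance requires at least 2 classes")
  }
  d <- stats::dist(mu)
  if (squared) d <- d^2
  mean(d)
}

#' Feature Adaptation Score of one layer
#'
#' Computes the three components (within-class variance, between-class
#' variance, mean between-class distance) and combines them into
#' `FAS = between/within + Dbar/sqrt(n)`, with `n` the embedding dimension
#' of the layer. A good few-shot layer has compact classes (small within),
#' spread-out class means (large between, large Dbar), hence a large FAS.
#'
#' @param fs A feature-set tibble with at least 2 classes.
#' @param layer_id Integer id recorded in the result (default `NA`).
#' @param scale_by `"dim"` (default) scales `Dbar` by the square root of the
#'   embedding dimension; `"count"` uses the sample count instead.
#' @param dbar_squared Use squared distances in `Dbar` (default `FALSE`).
#' @param eps Floor applied to the within-class variance before division
#'   (default `1e-12`); hitting the floor logs a warning.
#' @return A one-row tibble: `layer_id`, `within_var`, `between_var`,
#'   `mean_between_dist`, `dim`, `fas`.
#' @examples
#' fs <- feature_set(matrix(c(-1, 1, 1, 3)), c(0L, 0L, 1L, 1L))
#' fas_score(fs) # within 1, between 1, Dbar 2, n = 1 -> FAS 3
#' @export
fas_score <- function(fs, layer_id = NA_integer_, scale_by = c("dim", "count"),
                      dbar_squared = FALSE, eps = FAS_EPS) {
  fs <- validate_feature_set(fs)
  scale_by <- match.arg(scale_by)
  if (n_classes(fs) < 2) {
    abort_validation("fas_score requires at least 2 classes")
  }
  cm <- class_means(fs)
  wv <- within_class_variance(fs, cm)
  bv <- between_class_variance(cm)
  db <- mean_between_class_distance(cm, squared = dbar_squared)
  n <- if (scale_by == "dim") feature_dim(fs) else nrow(fs)
  if (wv < eps) {
    warn(paste0("within-class variance ", format(wv),
                " below floor ", format(eps), "; using the floor"))
  }
  tibble(
    layer_id = as.integer(layer_id),
    within_var = wv,
    between_var = bv,
    mean_between_dist = db,
    dim = as.integer(feature_dim(fs)),
    fas = bv / max(wv, eps) + db / sqrt(n)
  )
}

#' Score every layer of a bank and select the best
#'
#' @param bank A `layer_bank`.
#' @inheritParams fas_score
#' @return A `fas_report`: list with `components` (one [fas_score()] row per
#'   layer, in layer order) and `best_layer` (layer id with maximal FAS;
#'   ties go to the larger, i.e. deeper, layer id).
#' @examples
#' bank <- make_layer_series()
#' rep <- fas_layers(bank)
#' rep$best_layer
#' @export
fas_layers <- function(bank, scale_by = c("dim", "count"),
                       dbar_squared = FALSE, eps = FAS_EPS) {
  validate_layer_bank(bank)
  scale_by <- match.arg(scale_by)
  components <- purrr::map2(bank$data, bank$layer_id, function(d, l) {
    tryCatch(
      fas_score(d, layer_id = l, scale_by = scale_by,
                dbar_squared = dbar_squared, eps = eps),
      error = function(e) {
        abort_validation(paste0("layer ", l, ": ", conditionMessage(e)))
      })
  })
  components <- dplyr::bind_rows(components)
  report <- structure(
    list(components = components, best_layer = NA_integer_),
    class = "fas_report")
  report$best_layer <- select_best_layer(report)
  report
}

#' Layer with the maximal Feature Adaptation Score
#'
#' Ties are broken toward the larger layer id (the deeper layer).
#'
#' @param report A `fas_report` from [fas_layers()].
#' @return Integer layer id.
#' @export
select_best_layer <- function(report) {
  comp <- if (inherits(report, "fas_report")) report$components else as_tibble(report)
  if (is.null(comp) || nrow(comp) == 0) {
    abort_validation("empty FAS report")
  }
  best <- max(comp$fas)
  max(comp$layer_id[comp$fas == best])
}

#' @export
print.fas_report <- function(x, ...) {
  cat("Feature Adaptation Score report (", nrow(x$components), " layers)\n", sep = "")
  print(x$components)
  cat("best layer:", x$best_layer, "\n")
  invisible(x)
}
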