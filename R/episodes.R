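# N-way-K-shot episode machinery: sampling, prototype construction,
# nearest-prototype classification, and the repeated-runs evaluation
# protocol (accuracy plus pooled macro precision/recall/F1).

#' Define an N-way-K-shot episode specification
#'
#' @param n_way Number of classes per episode, N.
#' @param k_shot Labeled support examples per class, K.
#' @param q_per_class Query examples per class (the paper-style protocol
#'   leaves this open; 15 is the conventional default).
#' @param metric Distance used for classification: `"euclidean"` (default,
#'   the metric the calibration procedure assumes) or `"cosine"`.
#' @param seed Optional integer seed stored with the spec and used by
#'   [sample_episode()] when no explicit seed is given.
#' @return An `episode_spec` list.
#' @export
episode_spec <- function(n_way = 5, k_shot = 1, q_per_class = 15,
                         metric = c("euclidean", "cosine"), seed = NULL) {
  metric <- match.arg(metric)
  for (v in c(n_way = n_way, k_shot = k_shot, q_per_class = q_per_class)) {
    if (!is_count(v)) abort_validation("n_way, k_shot and q_per_class must be positive integers")
  }
  structure(list(n_way = as.integer(n_way), k_shot = as.integer(k_shot),
                 q_per_class = as.integer(q_per_class), metric = metric,
                 seed = seed),
            class = "episode_spec")
}

# Index structure reused across many episodes of one feature set.
episode_source <- function(fs, spec) {
  fs <- validate_feature_set(fs)
  m <- feature_matrix(fs)
  lab <- fs$label
  idx_by_class <- split(seq_along(lab), lab)
  need <- spec$k_shot + spec$q_per_class
  sizes <- lengths(idx_by_class)
  if (length(idx_by_class) < spec$n_way) {
    abort_validation(paste0("need at least ", spec$n_way, " classes, have ",
                            length(idx_by_class)))
  }
  if (any(sizes < need)) {
    bad <- names(idx_by_class)[sizes < need]
    abort_validation(paste0("class(es) ", paste(bad, collapse = ", "),
                            " have fewer than K + q = ", need, " samples"))
  }
  list(m = m, idx_by_class = idx_by_class, n_classes = length(idx_by_class))
}

# One episode as index sets; sampling is uniform without replacement at both
# levels (classes, then samples within class).
sample_episode_idx <- function(src, spec) {
  cls <- sort(sample.int(src$n_classes, spec$n_way))
  k <- spec$k_shot
  q <- spec$q_per_class
  sup <- integer(spec$n_way * k)
  qry <- integer(spec$n_way * q)
  for (i in seq_len(spec$n_way)) {
    pick <- sample(src$idx_by_class[[cls[i]]], k + q)
    sup[((i - 1) * k + 1):(i * k)] <- pick[1:k]
    qry[((i - 1) * q + 1):(i * q)] <- pick[(k + 1):(k + q)]
  }
  list(classes = cls, support = sup, query = qry)
}

#' Sample one N-way-K-shot episode
#'
#' Classes are drawn uniformly without replacement from the feature set,
#' then `k_shot + q_per_class` samples per class, split disjointly into
#' support and query. Class indices are remapped to `0..N-1`; `class_map`
#' records the original class of each episode index.
#'
#' @param fs A feature-set tibble.
#' @param spec An [episode_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. The same seed always
#'   yields the same episode.
#' @return An `episode`: list with `support_features`, `support_labels`,
#'   `query_features`, `query_labels`, `class_map`.
#' @export
sample_episode <- function(fs, spec, seed = spec$seed) {
  src <- episode_source(fs, spec)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample_episode_idx(src, spec)
  new_episode(src, idx, spec)
}

new_episode <- function(src, idx, spec) {
  structure(list(
    support_features = src$m[idx$support, , drop = FALSE],
    support_labels = rep(seq_len(spec$n_way) - 1L, each = spec$k_shot),
    query_features = src$m[idx$query, , drop = FALSE],
    query_labels = rep(seq_len(spec$n_way) - 1L, each = spec$q_per_class),
    class_map = as.integer(names(src$idx_by_class))[idx$classes],
    spec = spec
  ), class = "episode")
}

#' Euclidean (L2) distance between two vectors
#' @param a,b Numeric vectors of equal length.
#' @return `||a - b||_2`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) abort_validation("dimension mismatch")
  sqrt(sum((a - b)^2))
}

#' Cosine distance between two vectors
#'
#' `1 - cos(a, b)`, in `[0, 2]`; zero vectors are rejected.
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b)) abort_validation("dimension mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort_validation("cosine distance undefined for zero vectors")
  1 - sum(a * b) / (na * nb)
}

#' Class prototypes of an episode
#'
#' Row k is the mean of the class-k support embeddings; with K = 1 the
#' prototypes are the support rows themselves.
#'
#' @param ep An `episode`.
#' @return Numeric matrix, N rows in episode-class order `0..N-1`.
#' @export
compute_prototypes <- function(ep) {
  prototypes_of(ep$support_features, ep$support_labels)
}

prototypes_of <- function(features, labels) {
  p <- rowsum(features, labels, reorder = TRUE)
  p / as.vector(table(labels))
}

# Pairwise distance matrix queries x prototypes for the supported metrics.
query_dist <- function(queries, protos, metric) {
  if (ncol(queries) != ncol(protos)) abort_validation("dimension mismatch")
  if (metric == "euclidean") {
    d2 <- -2 * queries %*% t(protos)
    d2 <- sweep(d2, 2, rowSums(protos^2), "+") + rowSums(queries^2)
    sqrt(pmax(d2, 0))
  } else {
    qn <- sqrt(rowSums(queries^2)); pn <- sqrt(rowSums(protos^2))
    if (any(qn == 0) || any(pn == 0)) {
      abort_validation("cosine distance undefined for zero vectors")
    }
    1 - (queries %*% t(protos)) / outer(qn, pn)
  }
}

#' Classify queries against class prototypes
#'
#' Each query is assigned the class of its nearest prototype; exact ties go
#' to the smallest class index.
#'
#' @param protos N x n prototype matrix (row k = class k), e.g. from
#'   [compute_prototypes()], or a data frame with feature columns.
#' @param queries Query matrix or data frame with feature columns.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return Integer vector of predicted labels in `0..N-1`.
#' @export
classify_queries <- function(protos, queries, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (is.data.frame(protos)) protos <- feature_matrix(protos)
  if (is.data.frame(queries)) queries <- feature_matrix(queries)
  if (!is.matrix(queries)) queries <- matrix(queries, nrow = 1)
  d <- query_dist(queries, protos, metric)
  max.col(-d, ties.method = "first") - 1L
}

#' Episode accuracy
#' @param pred,truth Equal-length label vectors.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
episode_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) abort_validation("length mismatch")
  mean(pred == truth)
}

#' Macro-averaged precision, recall and F1
#'
#' Per-class precision, recall and F1 are computed from the confusion counts
#' and averaged with equal class weight. A zero denominator (class never
#' predicted, never occurring, or zero P+R) contributes 0, with a warning.
#'
#' @param pred,truth Label vectors with values in `0..n_classes-1`.
#' @param n_classes Number of classes N.
#' @return One-row tibble: `precision`, `recall`, `f1`.
#' @export
macro_metrics <- function(pred, truth, n_classes) {
  if (length(pred) != length(truth)) abort_validation("length mismatch")
  if (any(c(pred, truth) < 0) || any(c(pred, truth) >= n_classes)) {
    abort_validation("label out of range 0..n_classes-1")
  }
  conf <- table(factor(truth, levels = 0:(n_classes - 1)),
                factor(pred, levels = 0:(n_classes - 1)))
  macro_from_confusion(unclass(conf))
}

# conf[i, j] = count of truth i predicted j (classes in row/col order).
macro_from_confusion <- function(conf) {
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  safe_div <- function(num, den, what) {
    z <- den == 0
    if (any(z)) {
      warn(paste0("zero denominator in per-class ", what,
                  " for class(es) ", paste(which(z) - 1, collapse = ", "),
                  "; contributing 0"))
    }
    ifelse(z, 0, num / den)
  }
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  tibble(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

#' Run the repeated-episodes evaluation protocol
#'
#' Samples `episodes_per_run` episodes in each of `runs` independent runs
#' (the reference protocol is 1000 episodes averaged over 20 runs),
#' classifies every episode's queries against its (optionally calibrated)
#' support prototypes, and aggregates per-episode accuracy plus macro
#' precision/recall/F1 pooled over all episodes' confusion counts.
#'
#' Each run uses an RNG substream derived deterministically from `seed` and
#' the run index, so runs are reproducible individually and jointly.
#'
#' @param fs A feature-set tibble.
#' @param spec An [episode_spec()].
#' @param episodes_per_run Episodes sampled per run (default 1000).
#' @param runs Number of runs averaged (default 20).
#' @param calibrator Optional function applied to each episode's N x n
#'   prototype matrix before classification, e.g. [pdfc_calibrator()].
#' @param seed Integer seed for the whole protocol (default 1).
#' @return A `fewshot_eval` object; see [glance.fewshot_eval()] for the
#'   summary row and [tidy.fewshot_eval()] for the per-episode log.
#' @examples
#' fs <- make_gaussian_classes(gaussian_class_spec(n_classes = 6,
#'   samples_per_class = 20, dim = 8, within_scale = 0.05))
#' ev <- run_evaluation(fs, episode_spec(5, 1, 5), episodes_per_run = 20,
#'   runs = 2, seed = 1)
#' glance(ev)
#' @export
run_evaluation <- function(fs, spec, episodes_per_run = 1000, runs = 20,
                           calibrator = NULL, seed = 1) {
  if (!is_count(episodes_per_run) || !is_count(runs)) {
    abort_validation("episodes_per_run and runs must be positive integers")
  }
  src <- episode_source(fs, spec)
  n <- spec$n_way
  conf <- matrix(0, n, n)
  acc <- matrix(NA_real_, nrow = episodes_per_run, ncol = runs)
  truth <- rep(seq_len(n) - 1L, each = spec$q_per_class)
  sup_lab <- rep(seq_len(n) - 1L, each = spec$k_shot)
  for (r in seq_len(runs)) {
    set.seed(derive_seed(seed, r))
    for (e in seq_len(episodes_per_run)) {
      idx <- sample_episode_idx(src, spec)
      protos <- prototypes_of(src$m[idx$support, , drop = FALSE], sup_lab)
      if (!is.null(calibrator)) protos <- calibrator(protos)
      queries <- src$m[idx$query, , drop = FALSE]
      pred <- max.col(-query_dist(queries, protos, spec$metric),
                      ties.method = "first") - 1L
      acc[e, r] <- mean(pred == truth)
      conf <- conf + unclass(table(factor(truth, levels = 0:(n - 1)),
                                   factor(pred, levels = 0:(n - 1))))
    }
  }
  log <- tibble(
    run = rep(seq_len(runs), each = episodes_per_run),
    episode = rep(seq_len(episodes_per_run), times = runs),
    accuracy = as.vector(acc)
  )
  mm <- macro_from_confusion(conf)
  structure(list(
    summary = tibble(
      mean_accuracy = mean(acc), std_accuracy = sd(as.vector(acc)),
      macro_precision = mm$precision, macro_recall = mm$recall,
      macro_f1 = mm$f1,
      episodes_per_run = as.integer(episodes_per_run), runs = as.integer(runs)
    ),
    episode_log = log,
    confusion = conf,
    spec = spec,
    calibration = attr(calibrator, "params", exact = TRUE),
    seed = seed
  ), class = "fewshot_eval")
}

#' @export
print.fewshot_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d-way %d-shot evaluation: %d episodes x %d runs\n",
              x$spec$n_way, x$spec$k_shot, s$episodes_per_run, s$runs))
  cat(sprintf("  mean accuracy %.4f (sd %.4f)\n", s$mean_accuracy, s$std_accuracy))
  cat(sprintf("  macro P/R/F1  %.4f / %.4f / %.4f\n",
              s$macro_precision, s$macro_recall, s$macro_f1))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: m = %d, lambda = %g, gamma = %g\n",
                x$calibration$m, x$calibration$lam, x$calibration$gamma))
  }
  invisible(x)
}
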