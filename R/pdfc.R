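# Plant Disease Feature Calibration (PDFC): a training-free, non-parametric
# correction of support prototypes under domain shift. For each episode
# class, the m source-bank vectors nearest the prototype are averaged into a
# reference centroid; the prototype is then moved gamma feature-space units
# toward a point T interpolated (by lambda) between its two nearest
# centroids. Queries are finally classified against the shifted prototypes.

#' PDFC hyperparameters
#'
#' @param m Number of nearest reference vectors averaged per class centroid
#'   (default 10).
#' @param lam Interpolation coordinate lambda along the segment from the
#'   nearest centroid `c_a` (`lam = 0`) to the second-nearest `c_b`
#'   (`lam = 1`); values above 1 extrapolate along the line.
#' @param gamma Shift magnitude in feature-space units; the calibrated
#'   prototype lies exactly `gamma` from the original (it may overshoot T).
#' @return A `calibration_params` list.
#' @export
calibration_params <- function(m = 10, lam = 0, gamma = 0) {
  if (!is_count(m)) abort_validation("m must be a positive integer")
  if (!is_scalar_num(lam) || lam < 0) abort_validation("lam must be finite and >= 0")
  if (!is_scalar_num(gamma) || gamma < 0) abort_validation("gamma must be finite and >= 0")
  structure(list(m = as.integer(m), lam = lam, gamma = gamma),
            class = "calibration_params")
}

ref_matrix <- function(ref) {
  if (is.data.frame(ref)) feature_matrix(ref) else {
    m <- as.matrix(ref); storage.mode(m) <- "double"; m
  }
}

#' Reference centroid of one class
#'
#' L2 distances from every reference-bank row to the prototype are sorted
#' ascending; the centroid is the mean of the `m` nearest reference *rows*.
#' Ties at the m-th distance are broken by lower row index.
#'
#' @param ref Reference bank: a feature-set tibble or numeric matrix (labels,
#'   if any, are not used).
#' @param proto Numeric vector, the class prototype.
#' @param m Number of nearest rows to average.
#' @return List with `centroid` (numeric vector) and `indices` (the m row
#'   indices used, in ascending-distance order).
#' @export
class_reference_centroid <- function(ref, proto, m) {
  R <- ref_matrix(ref)
  if (!is_count(m)) abort_validation("m must be a positive integer")
  if (m > nrow(R)) {
    abort_validation(paste0("m = ", m, " exceeds reference bank size ", nrow(R)))
  }
  if (length(proto) != ncol(R)) abort_validation("dimension mismatch")
  d2 <- rowSums(R^2) - 2 * as.vector(R %*% proto) + sum(proto^2)
  idx <- order(d2)[seq_len(m)]
  list(centroid = colMeans(R[idx, , drop = FALSE]), indices = idx)
}

#' Reference centroids for all episode classes
#'
#' @param ref Reference bank (feature-set tibble or matrix).
#' @param protos N x n prototype matrix (row k = class k).
#' @param m Nearest reference rows per centroid.
#' @return A `centroid_bank`: list with `centroids` (N x n matrix) and
#'   `neighbor_indices` (list of the m bank rows behind each centroid).
#' @export
build_centroids <- function(ref, protos, m) {
  if (is.data.frame(protos)) protos <- feature_matrix(protos)
  res <- lapply(seq_len(nrow(protos)), function(i) {
    tryCatch(class_reference_centroid(ref, protos[i, ], m),
             error = function(e) {
               abort_validation(paste0("class ", i - 1, ": ", conditionMessage(e)))
             })
  })
  structure(list(
    centroids = do.call(rbind, lapply(res, `[[`, "centroid")),
    neighbor_indices = lapply(res, `[[`, "indices")
  ), class = "centroid_bank")
}

#' Interpolated calibration target T for one prototype
#'
#' Distances from the prototype to all N centroids identify the nearest,
#' `c_a`, and second nearest, `c_b` (ties by lower class index);
#' `T = (1 - lam) * c_a + lam * c_b`.
#'
#' @param proto Numeric vector.
#' @param cb A `centroid_bank` (or plain centroid matrix) with >= 2 rows.
#' @param lam Interpolation coordinate.
#' @return List with `target` (T), `a` and `b` (0-based class indices of the
#'   two nearest centroids).
#' @export
calibration_target <- function(proto, cb, lam) {
  cent <- if (inherits(cb, "centroid_bank")) cb$centroids else as.matrix(cb)
  if (nrow(cent) < 2) {
    abort_validation("calibration_target requires at least 2 centroids")
  }
  d2 <- rowSums(sweep(cent, 2, proto)^2)
  o <- order(d2)  # stable: ties resolved toward the lower index
  a <- o[1]; b <- o[2]
  list(target = (1 - lam) * cent[a, ] + lam * cent[b, ],
       a = a - 1L, b = b - 1L)
}

#' Shift a prototype toward a target point
#'
#' Moves `gamma` units along the unit vector from the prototype toward `T`;
#' if the prototype already coincides with `T` (within 1e-12) it is returned
#' unchanged.
#'
#' @param proto,target Numeric vectors of equal length.
#' @param gamma Non-negative step length.
#' @return The shifted vector.
#' @export
shift_prototype <- function(proto, target, gamma) {
  if (length(proto) != length(target)) abort_validation("dimension mismatch")
  if (any(!is.finite(proto)) || any(!is.finite(target))) {
    abort_validation("non-finite input")
  }
  v <- target - proto
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12 || gamma == 0) return(proto)
  proto + gamma * v / nv
}

# Core of the algorithm, shared by the user-facing wrappers and the
# evaluation-harness calibrator: prototypes in, calibrated prototypes out.
# The per-query loop of the original formulation is hoisted out: the
# calibration does not depend on the query, so it is computed once per
# episode. neighbor_mode "a" measures prototype-to-centroid distances;
# "b" the transposed reading (centroid-to-prototype).
calibrate_prototypes <- function(protos, ref, params,
                                 neighbor_mode = c("a", "b")) {
  neighbor_mode <- match.arg(neighbor_mode)
  cb <- build_centroids(ref, protos, params$m)
  n <- nrow(protos)
  out <- protos
  prov <- vector("list", n)
  for (i in seq_len(n)) {
    tgt <- if (neighbor_mode == "a") {
      calibration_target(protos[i, ], cb, params$lam)
    } else {
      # reading (B): rank prototypes by distance from this class's centroid,
      # then interpolate between the centroids of the two nearest classes.
      d2 <- rowSums(sweep(protos, 2, cb$centroids[i, ])^2)
      o <- order(d2)
      a <- o[1]; b <- o[2]
      list(target = (1 - params$lam) * cb$centroids[a, ] +
             params$lam * cb$centroids[b, ],
           a = a - 1L, b = b - 1L)
    }
    out[i, ] <- shift_prototype(protos[i, ], tgt$target, params$gamma)
    prov[[i]] <- tgt
  }
  structure(list(prototypes = out, original = protos, params = params,
                 provenance = prov, centroids = cb),
            class = "calibrated_support")
}

#' Calibrate an episode's support prototypes against a reference bank
#'
#' For K > 1 the class prototypes (support means) are formed first, then
#' each prototype is calibrated: reference centroids from its m nearest
#' bank vectors, target T between its two nearest centroids, shift of
#' gamma units toward T. The calibration is query-independent and computed
#' once per episode.
#'
#' @param ep An `episode`.
#' @param ref Reference bank (feature-set tibble or matrix).
#' @param params A [calibration_params()].
#' @param neighbor_mode `"a"` (default): the two nearest centroids of each
#'   *prototype* define T; `"b"`: the transposed reading, ranking prototypes
#'   by distance from the class centroid.
#' @return A `calibrated_support`: `prototypes` (N x n), `original`,
#'   `params`, and per-class `provenance` (`a`, `b`, `target`).
#' @export
calibrate_episode <- function(ep, ref, params, neighbor_mode = c("a", "b")) {
  protos <- compute_prototypes(ep)
  calibrate_prototypes(protos, ref, params, neighbor_mode)
}

#' Classify an episode's queries with PDFC calibration
#'
#' Runs [calibrate_episode()] and assigns each query to the calibrated
#' prototype with the smallest L2 distance (ties to the lowest class
#' index). With `gamma = 0` this is exactly the uncalibrated
#' nearest-prototype classifier.
#'
#' @inheritParams calibrate_episode
#' @return Integer predicted labels in `0..N-1`.
#' @export
pdfc_classify <- function(ep, ref, params, neighbor_mode = c("a", "b")) {
  cal <- calibrate_episode(ep, ref, params, neighbor_mode)
  classify_queries(cal$prototypes, ep$query_features, metric = "euclidean")
}

#' Calibrator closure for the evaluation harness
#'
#' Wraps a reference bank and parameter set into the prototype-transforming
#' function [run_evaluation()] expects.
#'
#' @inheritParams calibrate_episode
#' @param ref Reference bank (feature-set tibble or matrix).
#' @return A function mapping an N x n prototype matrix to its calibrated
#'   version, with the parameters attached as attribute `"params"`.
#' @export
pdfc_calibrator <- function(ref, params, neighbor_mode = c("a", "b")) {
  neighbor_mode <- match.arg(neighbor_mode)
  R <- ref_matrix(ref)
  f <- function(protos) {
    calibrate_prototypes(protos, R, params, neighbor_mode)$prototypes
  }
  attr(f, "params") <- params
  f
}
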