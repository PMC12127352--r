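# Synthetic Gaussian feature generators with known ground truth. They
# emulate the statistical structure the scoring and calibration methods
# assume: per-class multivariate normal embeddings, an ordered series of
# layers of differing separability, and a source/target pair related by a
# global bias plus extra noise (covariate shift).

#' Specification of a multi-class Gaussian feature set
#'
#' Class means are placed deterministically (given the seed) at
#' `between_scale` times maximally spread unit directions: a seeded random
#' orthonormal basis, completed by normalized Gaussian draws when there are
#' more classes than dimensions. Samples are the class mean plus isotropic
#' `within_scale` Gaussian noise.
#'
#' @param n_classes Number of classes (default 10).
#' @param samples_per_class Samples per class (default 30).
#' @param dim Embedding dimension (default 64).
#' @param between_scale Radius of the sphere holding the class means
#'   (default 1).
#' @param within_scale Isotropic within-class standard deviation per
#'   dimension (default 0.25).
#' @param seed Integer seed (default 1).
#' @return A `gaussian_class_spec` list.
#' @export
gaussian_class_spec <- function(n_classes = 10, samples_per_class = 30,
                                dim = 64, between_scale = 1,
                                within_scale = 0.25, seed = 1) {
  for (v in c(n_classes = n_classes, samples_per_class = samples_per_class, dim = dim)) {
    if (!is_count(v)) abort_validation("counts must be positive integers")
  }
  for (v in c(between_scale = between_scale, within_scale = within_scale)) {
    if (!is_scalar_num(v) || v < 0) abort_validation("scales must be finite and >= 0")
  }
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 dim = as.integer(dim), between_scale = between_scale,
                 within_scale = within_scale, seed = as.integer(seed)),
            class = "gaussian_class_spec")
}

# Deterministic maximally-spread unit directions: orthonormal while
# n_classes <= dim, then normalized Gaussian directions.
class_directions <- function(n_classes, dim, seed) {
  set.seed(seed)
  g <- matrix(rnorm(dim * max(n_classes, dim)), ncol = max(n_classes, dim))
  q <- qr.Q(qr(g[, seq_len(min(n_classes, dim)), drop = FALSE]))
  dirs <- t(q)
  if (n_classes > dim) {
    extra <- matrix(rnorm((n_classes - dim) * dim), ncol = dim)
    extra <- extra / sqrt(rowSums(extra^2))
    dirs <- rbind(dirs, extra)
  }
  dirs
}

class_mean_matrix <- function(spec) {
  spec$between_scale * class_directions(spec$n_classes, spec$dim, spec$seed)
}

#' Generate a multi-class Gaussian feature set
#'
#' @param spec A [gaussian_class_spec()].
#' @param class_prefix Prefix for the generated class names.
#' @return A feature-set tibble, fully reproducible per seed. The true class
#'   mean matrix is attached as attribute `"true_means"`.
#' @examples
#' fs <- make_gaussian_classes(gaussian_class_spec(n_classes = 3,
#'   samples_per_class = 5, dim = 4))
#' dplyr::count(fs, label)
#' @export
make_gaussian_classes <- function(spec = gaussian_class_spec(),
                                  class_prefix = "class") {
  mu <- class_mean_matrix(spec)
  set.seed(derive_seed(spec$seed, 1))
  per <- spec$samples_per_class
  lab <- rep(seq_len(spec$n_classes) - 1L, each = per)
  x <- mu[lab + 1L, , drop = FALSE] +
    spec$within_scale * matrix(rnorm(length(lab) * spec$dim), ncol = spec$dim)
  fs <- feature_set(x, lab,
                    class_names = paste0(class_prefix, seq_len(spec$n_classes) - 1L))
  attr(fs, "true_means") <- mu
  fs
}

#' Generate an ordered layer series of varying separability
#'
#' Layer k reuses the base spec with `between_scale * separabilities[k]` and
#' dimension `dims[k]`; all layers share the same label vector and sample
#' ids, as the embeddings of one sample set captured at several depths
#' would. The default series is monotone then peaked at layer 6 of 7,
#' mimicking a deep backbone whose late-middle block separates classes
#' best while the final block over-specializes.
#'
#' @param base A [gaussian_class_spec()] giving classes, samples, noise and
#'   base separation.
#' @param separabilities Per-layer multipliers of `between_scale`.
#' @param dims Per-layer embedding dimensions.
#' @return A `layer_bank` with attributes `"designed_peak"` (the layer id
#'   with maximal separability; ties toward the deeper layer) and
#'   `"separabilities"`.
#' @export
make_layer_series <- function(base = gaussian_class_spec(),
                              separabilities = c(0.25, 0.35, 0.5, 0.65, 0.8, 1.2, 0.55),
                              dims = rep(base$dim, length(separabilities))) {
  if (length(separabilities) != length(dims)) {
    abort_validation("separabilities and dims must have equal length")
  }
  layers <- purrr::map2(seq_along(dims), dims, function(k, d) {
    sp <- base
    sp$dim <- as.integer(d)
    sp$between_scale <- base$between_scale * separabilities[k]
    sp$seed <- derive_seed(base$seed, 100 + k)
    make_gaussian_classes(sp)
  })
  # all layers describe the same samples: unify ids and labels from layer 1
  ids <- layers[[1]]$sample_id
  layers <- lapply(layers, function(l) { l$sample_id <- ids; l })
  bank <- layer_bank(layers, layer_ids = seq_along(layers))
  attr(bank, "designed_peak") <- max(which(separabilities == max(separabilities)))
  attr(bank, "separabilities") <- separabilities
  bank
}

#' Specification of a source/target covariate-shift pair
#'
#' The reference (source) bank is drawn from the base class Gaussians; the
#' target set shares the same class means but every sample is displaced by
#' one fixed global bias vector of norm `bias_norm` and carries additional
#' isotropic noise of scale `extra_noise`. The defaults describe a tight,
#' curated source domain and a noisier field-style target.
#'
#' @param base A [gaussian_class_spec()] for the source domain; the default
#'   uses a small within-class scale (0.08) typical of a curated bank.
#' @param bank_size_per_class Source samples per class in the reference
#'   bank (default 100).
#' @param bias_norm Norm of the global target offset (default 3x the base
#'   within-class scale).
#' @param extra_noise Additional per-dimension noise scale in the target
#'   (default 0.25).
#' @param seed Integer seed (default `base$seed`).
#' @return A `shift_spec` list.
#' @export
shift_spec <- function(base = gaussian_class_spec(within_scale = 0.08),
                       bank_size_per_class = 100,
                       bias_norm = 3 * base$within_scale,
                       extra_noise = 0.25, seed = base$seed) {
  if (!is_count(bank_size_per_class)) {
    abort_validation("bank_size_per_class must be a positive integer")
  }
  for (v in c(bias_norm = bias_norm, extra_noise = extra_noise)) {
    if (!is_scalar_num(v) || v < 0) abort_validation("scales must be finite and >= 0")
  }
  structure(list(base = base,
                 bank_size_per_class = as.integer(bank_size_per_class),
                 bias_norm = bias_norm, extra_noise = extra_noise,
                 seed = as.integer(seed)),
            class = "shift_spec")
}

#' Generate a reference bank and a shifted target feature set
#'
#' @param spec A [shift_spec()].
#' @return A list with `reference` (source-domain feature set, labels kept
#'   for diagnostics), `target` (shifted feature set), `bias` (the true
#'   global offset vector, `attr(, "true_means")` on both sets giving the
#'   class means), fully reproducible per seed.
#' @examples
#' pair <- make_shift_pair(shift_spec(bias_norm = 0, extra_noise = 0))
#' sqrt(sum(pair$bias^2))
#' @export
make_shift_pair <- function(spec = shift_spec()) {
  base <- spec$base
  mu <- class_mean_matrix(base)
  ref_spec <- base
  ref_spec$samples_per_class <- spec$bank_size_per_class
  ref_spec$seed <- base$seed
  ref <- make_gaussian_classes(ref_spec, class_prefix = "source")

  set.seed(derive_seed(spec$seed, 2))
  b <- rnorm(base$dim)
  b <- if (spec$bias_norm == 0) b * 0 else b / sqrt(sum(b^2)) * spec$bias_norm
  per <- base$samples_per_class
  lab <- rep(seq_len(base$n_classes) - 1L, each = per)
  sd_t <- sqrt(base$within_scale^2 + spec$extra_noise^2)
  x <- mu[lab + 1L, , drop = FALSE] +
    sd_t * matrix(rnorm(length(lab) * base$dim), ncol = base$dim)
  x <- sweep(x, 2, b, "+")
  target <- feature_set(x, lab,
                        class_names = paste0("target", seq_len(base$n_classes) - 1L))
  attr(target, "true_means") <- mu
  list(reference = ref, target = target, bias = b)
}
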