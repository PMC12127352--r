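# Bridge from image folders to layer feature banks. Ships a deterministic
# "toy" backbone (seeded fixed random projections with rectification) so the
# whole pipeline is testable without pretrained weights; any real backbone
# can be plugged in through the same handle contract.

#' List an image dataset organized as one directory per class
#'
#' Class indices are contiguous from 0 in sorted class-name order; traversal
#' is fully deterministic.
#'
#' @param root Directory containing one subdirectory per class with PNG
#'   images inside.
#' @return An `image_manifest` tibble: `sample_id`, `path`, `class_name`,
#'   `label`, with the root stored as attribute `"root"`.
#' @export
list_image_dataset <- function(root) {
  if (!dir.exists(root)) abort_validation(paste0("no such directory: ", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) {
    abort_validation(paste0("no class subdirectories under ", root))
  }
  recs <- purrr::imap(classes, function(cl, i) {
    files <- sort(list.files(file.path(root, cl), pattern = "\\.png$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) {
      abort_validation(paste0("class directory has no PNG images: ",
                              file.path(root, cl)))
    }
    tibble(path = files, class_name = cl, label = i - 1L)
  })
  out <- dplyr::bind_rows(recs)
  out <- dplyr::mutate(out,
    sample_id = paste0(.data$class_name, "/", basename(.data$path)),
    .before = 1)
  attr(out, "root") <- root
  class(out) <- c("image_manifest", class(out))
  out
}

# Decode a PNG to a grayscale matrix in [0, 1]; errors name the file.
decode_image <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such image file: ", path))
  img <- tryCatch(png::readPNG(path), error = function(e) {
    abort_validation(paste0("cannot decode image: ", path))
  })
  if (length(dim(img)) == 3) {
    k <- min(dim(img)[3], 3)
    img <- apply(img[, , seq_len(k), drop = FALSE], c(1, 2), mean)
  }
  img
}

# Nearest-neighbor resize to a fixed square side.
resize_gray <- function(img, side) {
  ri <- pmin(pmax(round(seq(1, nrow(img), length.out = side)), 1), nrow(img))
  ci <- pmin(pmax(round(seq(1, ncol(img), length.out = side)), 1), ncol(img))
  img[ri, ci, drop = FALSE]
}

#' Deterministic toy backbone
#'
#' A stack of seeded fixed random projections with rectification: images are
#' decoded, resized to `side` x `side` grayscale, flattened, and passed
#' through `depth` layers `h_l = max(0, W_l h_{l-1})` whose weights are
#' drawn once from the seed. Identical images always give identical
#' features; it learns nothing and exists so the extraction, scoring and
#' evaluation pipeline can be exercised end to end.
#'
#' @param seed Integer seed fixing all weights.
#' @param dims Output dimension of each layer (its length is the depth).
#' @param side Square side images are resized to before flattening
#'   (default 32).
#' @return A `backbone_handle`: `name`, `layer_ids`, `dims`, and
#'   `features(paths, layers)` returning one matrix per requested layer.
#' @export
toy_backbone <- function(seed = 1, dims = c(16, 16, 32, 32, 64, 64, 32),
                         side = 32) {
  dims <- as.integer(dims)
  if (length(dims) < 1 || any(dims < 1)) abort_validation("invalid dims")
  in_dims <- c(side * side, dims[-length(dims)])
  weights <- lapply(seq_along(dims), function(l) {
    set.seed(derive_seed(seed, l))
    matrix(rnorm(dims[l] * in_dims[l]) / sqrt(in_dims[l]), nrow = dims[l])
  })
  # each image runs through the stack on its own, so results are identical
  # bit for bit no matter how callers batch the paths
  forward_one <- function(p, layers) {
    h <- as.vector(resize_gray(decode_image(p), side))
    out <- vector("list", length(layers))
    for (l in seq_along(dims)) {
      h <- pmax(as.vector(weights[[l]] %*% h), 0)
      hit <- match(l, layers)
      if (!is.na(hit)) out[[hit]] <- h
    }
    out
  }
  features <- function(paths, layers) {
    per_image <- lapply(paths, forward_one, layers = layers)
    lapply(seq_along(layers), function(j) {
      do.call(rbind, lapply(per_image, `[[`, j))
    })
  }
  structure(list(name = "toy", layer_ids = seq_along(dims), dims = dims,
                 side = side, features = features),
            class = "backbone_handle")
}

#' Extract a layer feature bank from an image manifest
#'
#' Runs the backbone over the manifest in batches (batching is invisible in
#' the result) and assembles one feature set per requested layer, labels
#' and row order taken from the manifest.
#'
#' @param bb A backbone handle, e.g. [toy_backbone()].
#' @param manifest An [list_image_dataset()] manifest.
#' @param layers Layer ids to extract (default: all of `bb$layer_ids`).
#' @param batch_size Images per backbone call (default 16).
#' @return A `layer_bank`.
#' @export
extract_features <- function(bb, manifest, layers = bb$layer_ids,
                             batch_size = 16) {
  layers <- as.integer(layers)
  unknown <- setdiff(layers, bb$layer_ids)
  if (length(unknown) > 0) {
    abort_validation(paste0("unknown layer id(s): ", paste(unknown, collapse = ", ")))
  }
  n <- nrow(manifest)
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  parts <- lapply(batches, function(ii) bb$features(manifest$path[ii], layers))
  class_names <- unique(manifest$class_name[order(manifest$label)])
  sets <- lapply(seq_along(layers), function(j) {
    m <- do.call(rbind, lapply(parts, `[[`, j))
    rownames(m) <- NULL
    feature_set(m, manifest$label, class_names = class_names,
                sample_ids = manifest$sample_id)
  })
  layer_bank(sets, layer_ids = layers)
}
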