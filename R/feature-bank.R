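#' Build a layer feature bank
#'
#' A layer bank collects the embeddings of the *same* samples captured at
#' several depths of one backbone: one feature set per layer, all sharing an
#' identical `sample_id` order and label vector, with strictly increasing
#' layer ids. It is a tibble with one row per layer (`layer_id`, `dim`,
#' `data` list-column of feature sets), so layers can be mapped over with
#' purrr and joined to per-layer results.
#'
#' @param layers A list of feature-set tibbles, or a single feature set.
#' @param layer_ids Integer ids of the layers, strictly increasing; defaults
#'   to `1..L` or the names of `layers`.
#' @return A validated `layer_bank` tibble.
#' @examples
#' fs <- feature_set(matrix(rnorm(8), 4, 2), c(0L, 0L, 1L, 1L))
#' bank <- layer_bank(list(fs, fs))
#' bank$dim
#' @export
layer_bank <- function(layers, layer_ids = NULL) {
  if (is.data.frame(layers)) layers <- list(layers)
  if (is.null(layer_ids)) {
    layer_ids <- if (!is.null(names(layers)) && all(names(layers) != "")) {
      as.integer(names(layers))
    } else {
      seq_along(layers)
    }
  }
  bank <- tibble(
    layer_id = as.integer(layer_ids),
    dim = vapply(layers, feature_dim, integer(1)),
    data = lapply(layers, as_tibble)
  )
  class(bank) <- c("layer_bank", class(bank))
  validate_layer_bank(bank)
}

#' Validate the invariants of a layer bank
#'
#' Every layer must be a valid feature set; all layers must share the same
#' row count, sample ids and label vector; layer ids must be strictly
#' increasing.
#'
#' @param bank A `layer_bank` tibble.
#' @return `bank` if valid, else a validation error naming the rule.
#' @export
validate_layer_bank <- function(bank) {
  if (nrow(bank) == 0) abort_validation("invariant 'bank has at least one layer' violated")
  if (any(diff(bank$layer_id) <= 0)) {
    abort_validation("invariant 'layer_ids strictly increasing' violated")
  }
  lapply(bank$data, validate_feature_set)
  labs <- lapply(bank$data, function(d) d$label)
  ids <- lapply(bank$data, function(d) d$sample_id)
  if (length(unique(vapply(bank$data, nrow, integer(1)))) != 1 ||
      !all(vapply(labs, identical, logical(1), labs[[1]]))) {
    abort_validation(
      "invariant 'every layer has identical row count and label vector' violated")
  }
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    abort_validation("invariant 'every layer shares the same sample_ids' violated")
  }
  bank
}

#' Look up one layer of a bank
#' @param bank A `layer_bank`.
#' @param layer_id Integer id of the layer to extract.
#' @return The layer's feature-set tibble.
#' @export
bank_layer <- function(bank, layer_id) {
  i <- match(layer_id, bank$layer_id)
  if (is.na(i)) {
    abort_validation(paste0("layer_id ", layer_id, " not present in bank"))
  }
  bank$data[[i]]
}

# ---- HDF5 serialization --------------------------------------------------
# Layout: group /layer_<l> with dataset `features` (float32, M x n); root
# datasets `labels` (int32, M), `sample_ids` (UTF-8, M), `class_names`
# (UTF-8, C, optional); root attribute format_version = "1".

#' Write a layer bank to an HDF5 file
#'
#' Features are stored as 32-bit floats (typical backbone output precision);
#' all statistics elsewhere in the package are computed in doubles. Writing
#' the same bank twice produces byte-identical files.
#'
#' @param bank A validated `layer_bank`.
#' @param path Output file path; overwritten if present.
#' @return `path`, invisibly.
#' @export
write_feature_bank <- function(bank, path) {
  validate_layer_bank(bank)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_validation(paste0("output directory does not exist: ", dir))
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  first <- bank$data[[1]]
  rhdf5::h5write(as.integer(first$label), path, "labels")
  rhdf5::h5write(as.character(first$sample_id), path, "sample_ids")
  if ("class_name" %in% names(first)) {
    cn <- unique(first[order(first$label), ][["class_name"]])
    rhdf5::h5write(as.character(cn), path, "class_names")
  }
  for (i in seq_len(nrow(bank))) {
    grp <- paste0("layer_", bank$layer_id[i])
    rhdf5::h5createGroup(path, grp)
    m <- feature_matrix(bank$data[[i]])
    rhdf5::h5createDataset(path, paste0(grp, "/features"), dims = dim(m),
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(m, path, paste0(grp, "/features"))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("1", fid, "format_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a layer bank from an HDF5 file
#'
#' Malformed files (missing datasets, non-finite values, label/row
#' mismatches) raise a format error naming the offending dataset rather
#' than being silently coerced.
#'
#' @param path Path to a file written by [write_feature_bank()].
#' @return A validated `layer_bank`.
#' @export
read_feature_bank <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  on.exit(rhdf5::H5close(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  root <- ls$name[ls$group == "/"]
  if (!"labels" %in% root) abort_format("missing dataset 'labels'")
  if (!"sample_ids" %in% root) abort_format("missing dataset 'sample_ids'")
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  sample_ids <- as.character(rhdf5::h5read(path, "sample_ids"))
  class_names <- if ("class_names" %in% root) {
    as.character(rhdf5::h5read(path, "class_names"))
  }
  groups <- grep("^layer_[0-9]+$", root, value = TRUE)
  if (length(groups) == 0) abort_format("no 'layer_<l>' groups found")
  lids <- sort(as.integer(sub("^layer_", "", groups)))
  layers <- lapply(lids, function(l) {
    ds <- paste0("layer_", l, "/features")
    if (!any(ls$group == paste0("/layer_", l) & ls$name == "features")) {
      abort_format(paste0("missing dataset '", ds, "'"))
    }
    m <- rhdf5::h5read(path, ds)
    if (!is.matrix(m)) m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (nrow(m) != length(labels)) {
      abort_format(paste0("dataset '", ds, "' row count does not match 'labels'"))
    }
    if (anyNA(m) || any(!is.finite(m))) {
      abort_format(paste0("dataset '", ds, "' contains non-finite values"))
    }
    feature_set(m, labels, class_names = class_names, sample_ids = sample_ids)
  })
  layer_bank(layers, layer_ids = lids)
}

# ---- TSV dialect (single layer) ------------------------------------------

#' Write a single-layer feature set as TSV
#'
#' Tab-separated, header `sample_id label f1 ... fn`, UTF-8, Unix newlines.
#' Features are rounded to float32 storage precision and printed with enough
#' digits to round-trip that precision exactly, so read-then-rewrite is
#' byte-identical.
#'
#' @param fs A feature-set tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fs, path) {
  fs <- validate_feature_set(fs)
  cols <- feature_cols(fs)
  m <- as_float32(feature_matrix(fs))
  body <- apply(m, 1, function(r) paste(sprintf("%.9g", r), collapse = "\t"))
  lines <- c(
    paste(c("sample_id", "label", cols), collapse = "\t"),
    paste(fs$sample_id, fs$label, body, sep = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a single-layer feature set from TSV
#'
#' @param path Path to a TSV file in the dialect of [write_feature_tsv()].
#' @return A validated feature-set tibble.
#' @export
read_feature_tsv <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_format(paste0("cannot parse TSV: ", conditionMessage(e)))
  )
  need <- c("sample_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort_format(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  tryCatch(validate_feature_set(df),
           error = function(e) abort_format(conditionMessage(e)))
}
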