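# broom-style tidiers for the package's result objects.

#' Tidy a FAS report into its per-layer components
#'
#' @param x A `fas_report` from [fas_layers()].
#' @param ... Unused.
#' @return Tibble with one row per layer: components and total FAS.
#' @export
tidy.fas_report <- function(x, ...) {
  x$components
}

#' One-row summary of a FAS report
#'
#' @param x A `fas_report`.
#' @param ... Unused.
#' @return Tibble: `n_layers`, `best_layer`, `best_fas`.
#' @export
glance.fas_report <- function(x, ...) {
  tibble(n_layers = nrow(x$components),
         best_layer = x$best_layer,
         best_fas = max(x$components$fas))
}

#' Per-episode log of an evaluation
#'
#' @param x A `fewshot_eval` from [run_evaluation()].
#' @param ... Unused.
#' @return Tibble: `run`, `episode`, `accuracy`.
#' @export
tidy.fewshot_eval <- function(x, ...) {
  x$episode_log
}

#' One-row summary of an evaluation
#'
#' @param x A `fewshot_eval`.
#' @param ... Unused.
#' @return Tibble with mean/sd accuracy, macro precision/recall/F1 and the
#'   protocol counts.
#' @export
glance.fewshot_eval <- function(x, ...) {
  x$summary
}

#' Trial log of a hyperparameter search
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return Tibble of trials in evaluation order: `iteration`, `lam`,
#'   `gamma`, `objective`.
#' @export
tidy.search_result <- function(x, ...) {
  x$trials
}

#' One-row summary of a hyperparameter search
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return Tibble: `method`, `n_trials`, `best_lam`, `best_gamma`,
#'   `best_objective`.
#' @export
glance.search_result <- function(x, ...) {
  tibble(method = x$method, n_trials = nrow(x$trials),
         best_lam = x$best_params$lam, best_gamma = x$best_params$gamma,
         best_objective = x$best_objective)
}

#' Per-class view of a calibrated support set
#'
#' @param x A `calibrated_support` from [calibrate_episode()].
#' @param ... Unused.
#' @return Tibble: `class`, nearest/second centroid indices `a`, `b`, and
#'   the displacement norm actually applied.
#' @export
tidy.calibrated_support <- function(x, ...) {
  tibble(
    class = seq_len(nrow(x$prototypes)) - 1L,
    a = vapply(x$provenance, `[[`, integer(1), "a"),
    b = vapply(x$provenance, `[[`, integer(1), "b"),
    displacement = unname(sqrt(rowSums((x$prototypes - x$original)^2)))
  )
}
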