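# ggplot2 autoplot methods for the result objects.

#' Plot per-layer Feature Adaptation Scores
#'
#' @param object A `fas_report`.
#' @param ... Unused.
#' @return A ggplot: FAS against layer id, best layer highlighted.
#' @export
autoplot.fas_report <- function(object, ...) {
  comp <- object$components
  comp$best <- comp$layer_id == object$best_layer
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$layer_id, y = .data$fas)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "#D55E00"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = comp$layer_id) +
    ggplot2::labs(x = "layer", y = "Feature Adaptation Score",
                  title = paste0("FAS by layer (best: ", object$best_layer, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the episode-accuracy distribution of an evaluation
#'
#' @param object A `fewshot_eval`.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot histogram of per-episode accuracy with the mean marked.
#' @export
autoplot.fewshot_eval <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$episode_log, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$summary$mean_accuracy,
                        colour = "#D55E00", linewidth = 1) +
    ggplot2::labs(
      x = "episode accuracy", y = "episodes",
      title = sprintf("%d-way %d-shot: mean accuracy %.3f",
                      object$spec$n_way, object$spec$k_shot,
                      object$summary$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter search
#'
#' Grid results are drawn as an objective heatmap over (lambda, gamma);
#' Bayesian results as the best-so-far objective against iteration.
#'
#' @param object A `search_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.search_result <- function(object, ...) {
  tr <- object$trials
  if (object$method == "grid") {
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$lam, y = .data$gamma,
                                     fill = .data$objective)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = expression(lambda), y = expression(gamma),
                    fill = "objective", title = "Grid search") +
      ggplot2::theme_minimal()
  } else {
    tr$best_so_far <- cummax(ifelse(is.finite(tr$objective), tr$objective, -Inf))
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$best_so_far)) +
      ggplot2::geom_step(colour = "#0072B2") +
      ggplot2::geom_point(ggplot2::aes(y = .data$objective),
                          colour = "grey50", size = 1) +
      ggplot2::labs(x = "iteration", y = "objective",
                    title = "Bayesian search (best so far)") +
      ggplot2::theme_minimal()
  }
}
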