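#' Convergence curves of an experiment
#'
#' Mean best-so-far fitness per iteration for every algorithm, with the
#' individual runs drawn faintly behind.
#'
#' @param records An experiment tibble (see [run_experiment()]).
#' @return A ggplot object.
#' @export
plot_convergence <- function(records) {
  long <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    tibble::tibble(algorithm = records$algorithm[i], run = records$run[i],
                   iteration = seq_along(records$convergence[[i]]),
                   best_fitness = records$convergence[[i]])
  })
  mean_curve <- long |>
    dplyr::group_by(.data$algorithm, .data$iteration) |>
    dplyr::summarise(best_fitness = mean(.data$best_fitness), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$best_fitness,
                                     colour = .data$algorithm)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$algorithm, .data$run)),
                       alpha = 0.2, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_curve, linewidth = 1) +
    ggplot2::labs(x = "Iteration", y = "Best fitness (MSE)",
                  colour = "Algorithm") +
    ggplot2::theme_minimal()
}

#' Box plot of best-per-run fitness by algorithm
#'
#' @param object An experiment tibble (see [run_experiment()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hsasca_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$algorithm, .data$best_fitness,
                                       fill = .data$algorithm)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Best fitness (MSE)") +
    ggplot2::theme_minimal()
}

#' Bar chart of a mean-absolute Shapley importance ranking
#'
#' @param ranking A [mean_abs_importance()] tibble.
#' @param top_n Number of features shown.
#' @return A ggplot object.
#' @export
plot_importance <- function(ranking, top_n = 12) {
  top <- utils::head(ranking, top_n)
  ggplot2::ggplot(top, ggplot2::aes(.data$mean_abs_shap,
                                    stats::reorder(.data$feature,
                                                   .data$mean_abs_shap))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean |SHAP| (target units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a SHAP dependence series
#'
#' @param dep A [dependence_data()] tibble.
#' @param feature Axis label for the feature.
#' @return A ggplot object.
#' @export
plot_dependence <- function(dep, feature = "feature value") {
  aes <- if ("color_value" %in% names(dep)) {
    ggplot2::aes(.data$feature_value, .data$shap_value,
                 colour = .data$color_value)
  } else {
    ggplot2::aes(.data$feature_value, .data$shap_value)
  }
  ggplot2::ggplot(dep, aes) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = feature, y = "SHAP value (target units)") +
    ggplot2::theme_minimal()
}
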