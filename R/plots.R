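# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-group XAlign score distributions
#'
#' Boxplots of the per-item scores grouped by a label column, the visual
#' companion to [aggregate_scores()].
#'
#' @param object An `xalign_scores` tibble from [score_saliency()].
#' @param group Grouping column to plot by; defaults to `"method"` when
#'   present, else `"tier"`, else all items pooled.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xalign_scores <- function(object, group = NULL, ...) {
  if (is.null(group)) {
    group <- if ("method" %in% names(object)) "method"
             else if ("tier" %in% names(object)) "tier" else NULL
  }
  if (is.null(group)) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = "all", y = .data$score)) +
        ggplot2::geom_boxplot() +
        ggplot2::labs(x = NULL, y = "XAlign score") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data[[group]], -.data$score, mean),
    y = .data$score
  )) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = group, y = "XAlign score") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity grid
#'
#' Mean score per group across the grid cells; stable method rankings appear
#' as non-crossing lines.
#'
#' @param object A `sensitivity_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_grid
#' @export
autoplot.sensitivity_grid <- function(object, ...) {
  if ("alpha" %in% names(object)) {
    object$cell <- sprintf("(%.1f,%.1f,%.1f)", object$alpha, object$beta,
                           object$gamma)
  } else {
    object$cell <- sprintf("k=%g,T=%g", object$k, object$t)
  }
  group <- setdiff(names(object),
                   c("alpha", "beta", "gamma", "k", "t", "mean_score", "rank",
                     "cell"))[1]
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$cell, y = .data$mean_score,
    colour = .data[[group]], group = .data[[group]]
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "grid cell", y = "mean XAlign", colour = group) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Raster plot of a spike record
#'
#' Timesteps on the x-axis, neurons on the y-axis, tiles where spikes occur.
#'
#' @param object A `spike_record` from [simulate_if()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spike_record
#' @export
autoplot.spike_record <- function(object, ...) {
  df <- tidy.spike_record(object)
  ggplot2::ggplot(df[df$spike == 1, ],
                  ggplot2::aes(x = .data$timestep, y = .data$neuron)) +
    ggplot2::geom_tile(fill = "black") +
    ggplot2::scale_x_continuous(limits = c(0.5, nrow(object$spikes) + 0.5)) +
    ggplot2::scale_y_continuous(limits = c(0.5, ncol(object$spikes) + 0.5)) +
    ggplot2::labs(x = "timestep", y = "neuron") +
    ggplot2::theme_minimal()
}
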