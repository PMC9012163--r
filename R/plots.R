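#' Cell-mean plot of a kinematic measure
#'
#' Group-level cell means with standard-error bars by bigram and stroke
#' direction, faceted by group — the customary display of a
#' Group x Direction x Bigram anticipation design.
#'
#' @param cells Cell table from [aggregate_cells()].
#' @param response Measure column (`"duration_s"`, `"trajectory_cm"` or
#'   `"n_peaks"`).
#' @return A ggplot object.
#' @export
plot_cell_means <- function(cells, response = "duration_s") {
  summ <- cells |>
    dplyr::group_by(.data$group, .data$direction, .data$bigram) |>
    dplyr::summarise(
      mean = mean(.data[[response]], na.rm = TRUE),
      se = stats::sd(.data[[response]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[response]]))),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$bigram, y = .data$mean,
    colour = .data$direction, group = .data$direction
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.15), size = 2) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.15)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.1, position = ggplot2::position_dodge(0.15)
    ) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "bigram", y = response, colour = "direction") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_cell_means Plot method for a pen trace: pen path
#'   coloured by pressure state.
#' @param object A [pen_trace()] (for `autoplot.pen_trace`).
#' @param ... Unused.
#' @method autoplot pen_trace
#' @export
autoplot.pen_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pen <- ifelse(df$p > 0.1, "down", "up")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$pen)) +
    ggplot2::geom_path(ggplot2::aes(group = 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param object A [spearman_matrix()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spearman_matrix
#' @export
autoplot.spearman_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)), size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
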