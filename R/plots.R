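#' Scatter of paired log2 fold changes with the prediction-interval band
#'
#' TV6-versus-TV1 interspecies log2 fold changes, optionally colored by
#' disproportionality category, with the fitted line and prediction band.
#'
#' @param pairs Contrast-pair table (`lfc_x`, `lfc_y`; a `category` column
#'   is used for color when present).
#' @param fit Optional `"pi_fit"` from [fit_lfc_regression()].
#' @param n_grid Number of x positions for the band.
#' @return A ggplot object.
#' @export
plot_lfc_pairs <- function(pairs, fit = NULL, n_grid = 200) {
  pairs <- pairs |> filter(!is.na(.data$lfc_x), !is.na(.data$lfc_y))
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$lfc_x, y = .data$lfc_y))
  if (!is.null(fit)) {
    xr <- range(pairs$lfc_x, na.rm = TRUE)
    band <- prediction_interval(fit, seq(xr[1], xr[2], length.out = n_grid))
    p <- p +
      ggplot2::geom_ribbon(
        data = band,
        ggplot2::aes(x = .data$x, ymin = .data$lo, ymax = .data$hi),
        inherit.aes = FALSE, fill = "grey80", alpha = 0.6
      ) +
      ggplot2::geom_line(
        data = band, ggplot2::aes(x = .data$x, y = .data$fit),
        inherit.aes = FALSE, linewidth = 0.4
      )
  }
  if ("category" %in% names(pairs)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$category),
                                 size = 0.6, alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  }
  p + ggplot2::labs(
    x = "log2FC jerboa vs mouse, TV1",
    y = "log2FC jerboa vs mouse, TV6"
  ) + ggplot2::theme_minimal()
}

#' Heat map of weekly change in normalized vertebral length
#'
#' @param changes Change table from [weekly_relative_change()].
#' @return A ggplot object (vertebra by interval tiles).
#' @export
plot_growth_heatmap <- function(changes) {
  ggplot2::ggplot(
    changes,
    ggplot2::aes(x = factor(.data$from_day), y = .data$vertebra,
                 fill = .data$delta)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "weekly change") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "interval start (days)", y = "tail vertebra") +
    ggplot2::theme_minimal()
}

#' @describeIn disproportionality Plot method: scatter with the fitted line,
#'   prediction band, and category colors.
#' @param object A `"disprop_result"`.
#' @param ... Unused.
#' @method autoplot disprop_result
#' @export
autoplot.disprop_result <- function(object, ...) {
  plot_lfc_pairs(object$categories, object$fit)
}
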