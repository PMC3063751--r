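#' Heatmap of per-residue coupling over the windows of a fluctuogram
#'
#' Residue-by-window tile plot of `k_I(t)`, the direct visual record of how
#' the mechanical coupling network evolves.
#'
#' @param object A fluctuogram from [compute_fluctuogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluctuogram <- function(object, ...) {
  rs <- residue_series(object)
  ggplot2::ggplot(rs, ggplot2::aes(.data$window, .data$residue, fill = .data$k_I)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(k[I])) +
    ggplot2::labs(
      x = "window", y = "residue",
      title = "Per-residue mechanical coupling over time"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a residue-by-window metric
#'
#' Generic tile plot for the long metric tables returned by [psi()],
#' [delta_k_consecutive()] and [conformational_change()].
#'
#' @param metric Tibble with columns `window`, `residue` and one value
#'   column.
#' @param value Name of the value column (default: first non-index column).
#' @return A ggplot object.
#' @export
plot_metric_heatmap <- function(metric, value = NULL) {
  if (is.null(value)) {
    value <- setdiff(names(metric), c("window", "residue", "n_bonds"))[1]
  }
  ggplot2::ggplot(
    metric,
    ggplot2::aes(.data$window, .data$residue, fill = .data[[value]])
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "window", y = "residue") +
    ggplot2::theme_minimal()
}

#' Eigenvector map of a sector assignment
#'
#' Scatter of alignment positions on eigenvectors 2 and 3 with the
#' selection circle and sector colouring.
#'
#' @param object A `sector_assignment` from [select_sectors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sector_assignment <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  circ <- tibble(
    t = seq(0, 2 * pi, length.out = 200)
  )
  circ$x <- cutoff * cos(circ$t); circ$y <- cutoff * sin(circ$t)
  ggplot2::ggplot(object, ggplot2::aes(.data$v2, .data$v3)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                       linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$sector))) +
    ggplot2::scale_colour_discrete(name = "sector", na.value = "grey80") +
    ggplot2::labs(x = "eigenvector 2", y = "eigenvector 3") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
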