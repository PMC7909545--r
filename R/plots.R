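#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a per-cell metric on the grid
#'
#' @param values A data frame with `cell` plus at least one value column.
#' @param grid A [grid_spec()].
#' @param metric Name of the value column to map (default: first).
#' @return A ggplot tile map.
#' @export
plot_cell_metric <- function(values, grid, metric = NULL) {
  stopifnot(is.data.frame(values), inherits(grid, "grid_spec"))
  metric <- metric %||% setdiff(names(values), "cell")[1]
  d <- dplyr::left_join(cell_centers(grid, values$cell), values,
                        by = "cell")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data[[metric]])) +
    ggplot2::geom_tile(width = grid$cell_size, height = grid$cell_size) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = metric, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn classify_cells Tile map of CANAPE categories (needs the
#'   grid the cells index into).
#' @param object,x A `canape_classification`.
#' @param grid A [grid_spec()].
#' @param ... Unused.
#' @method autoplot canape_classification
#' @export
autoplot.canape_classification <- function(object, grid, ...) {
  d <- dplyr::left_join(cell_centers(grid, object$cell),
                        tibble::as_tibble(object), by = "cell")
  pal <- c(not_significant = "grey85", neo = "#d7301f",
           paleo = "#0570b0", mixed = "#54278f", super = "#f6c200")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$category)) +
    ggplot2::geom_tile(width = grid$cell_size, height = grid$cell_size) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(title = "CANAPE endemism centres", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn percentile_cells Tile map of hotspot membership.
#' @param object A `hotspot_set`.
#' @param grid A [grid_spec()].
#' @param all_cells Optional ids of all occupied cells (background).
#' @param ... Unused.
#' @method autoplot hotspot_set
#' @export
autoplot.hotspot_set <- function(object, grid,
                                 all_cells = seq_len(n_cells(grid)) - 1L,
                                 ...) {
  d <- cell_centers(grid, all_cells)
  d$member <- d$cell %in% object$cells
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$member)) +
    ggplot2::geom_tile(width = grid$cell_size, height = grid$cell_size) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "#d7301f")) +
    ggplot2::labs(title = sprintf("%s %s (%s tail)", object$metric,
                                  object$level, object$tail),
                  x = NULL, y = NULL, fill = "member") +
    ggplot2::theme_minimal()
}

#' @describeIn null_pvalues Histogram of per-cell null p-values by metric.
#' @param object A `null_result`.
#' @param ... Unused.
#' @method autoplot null_result
#' @export
autoplot.null_result <- function(object, ...) {
  d <- tidy.null_result(object)
  d <- tidyr::pivot_longer(d, c("p_high", "p_low"), names_to = "tail",
                           values_to = "p")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "#0570b0") +
    ggplot2::facet_grid(tail ~ metric) +
    ggplot2::labs(x = "rank p-value", y = "cells") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_sar_error Coefficient dot-and-whisker plot (+/- 1.96
#'   standard errors).
#' @param object A `sar_fit`.
#' @param ... Unused.
#' @method autoplot sar_fit
#' @export
autoplot.sar_fit <- function(object, ...) {
  d <- tidy.sar_fit(object)
  d <- d[d$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "standardized coefficient", y = NULL,
                  subtitle = sprintf("lambda = %.3f, GR2 = %.2f",
                                     object$lambda, object$GR2)) +
    ggplot2::theme_minimal()
}

#' @describeIn moran_correlogram Plot Moran's I against distance class.
#' @param correlogram A [moran_correlogram()] tibble.
#' @export
plot_correlogram <- function(correlogram) {
  ggplot2::ggplot(correlogram,
                  ggplot2::aes(x = (.data$d_lower + .data$d_upper) / 2,
                               y = .data$moran_i)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$expectation),
                        linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance class midpoint", y = "Moran's I") +
    ggplot2::theme_minimal()
}
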