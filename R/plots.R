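# shared archetype palette: natural greens through production reds
archetype_palette <- function() {
  stats::setNames(c("#1b7837", "#5aae61", "#a6dba0", "#fee08b",
                    "#fdae61", "#f46d43", "#a50026"), ARCHETYPES)
}

#' Plot an archetype raster
#'
#' @param object An `archetype_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.archetype_raster <- function(object, ...) {
  d <- raster_to_tibble(object$labels, object$grid, value = "archetype")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$archetype)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = archetype_palette(), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)",
                  fill = "Archetype") +
    ggplot2::theme_minimal()
}

#' Plot the regional composition of an extent table
#'
#' Stacked shares of archetypes per region, the frequency-distribution view
#' of the accounting table.
#'
#' @param object An `extent_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.extent_table <- function(object, ...) {
  d <- object[object$region != "Total", , drop = FALSE] |>
    tidyr::pivot_longer(dplyr::all_of(ARCHETYPES), names_to = "archetype",
                        values_to = "extent")
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$extent,
                                  fill = .data$archetype)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
    ggplot2::scale_fill_manual(values = archetype_palette()) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Share of forest area (%)",
                  fill = "Archetype") +
    ggplot2::theme_minimal()
}

#' Heat-table of mean patch sizes
#'
#' @param object An `mps_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mps_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$archetype, .data$region_id,
                                       fill = .data$mps_ha)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$mps_ha)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = "Archetype", y = NULL, fill = "MPS (ha)") +
    ggplot2::theme_minimal()
}

#' Plot a slice assessment
#'
#' Two-panel view of the gradient assessment: per-slice archetype
#' composition (D-G) and per-slice wood-production distributions.
#'
#' @param object A `slice_assessment`.
#' @param which `"shares"` or `"wood_production"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slice_assessment <- function(object,
                                      which = c("shares", "wood_production"),
                                      ...) {
  which <- match.arg(which)
  if (which == "shares") {
    ggplot2::ggplot(object$shares,
                    ggplot2::aes(factor(.data$slice), .data$percent,
                                 fill = .data$archetype)) +
      ggplot2::geom_col() +
      ggplot2::scale_fill_manual(values = archetype_palette()) +
      ggplot2::labs(x = "Slice (south to north)",
                    y = "Share of D-G forest (%)", fill = "Archetype") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$samples,
                    ggplot2::aes(.data$group, .data$value)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::labs(x = "Slice", y = "Wood production (m3/ha/yr)") +
      ggplot2::theme_minimal()
  }
}
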