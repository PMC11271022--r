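# ggplot2 visualisations of landscapes, AOH maps and KBA scoping results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

ring_df <- function(rings) {
  if (is.data.frame(rings)) rings <- list(rings)
  dplyr::bind_rows(purrr::imap(rings, function(r, i) {
    tibble::tibble(x = r$x, y = r$y, ring = i)
  }))
}

#' @describeIn generate_island Elevation map with the coastline overlaid.
#' @param object An `island_landscape`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.island_landscape <- function(object, ...) {
  elev <- as_tibble.scape_raster(object$elevation)
  coast <- ring_df(object$coastline)
  ggplot2::ggplot(elev, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = coast,
                       ggplot2::aes(group = .data$ring), colour = "grey20",
                       linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "elevation (m)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", title = "Synthetic island landscape")
}

#' @describeIn build_aoh Habitat mask over the analysis domain.
#' @param object An `aoh_map`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.aoh_map <- function(object, ...) {
  h <- object$header
  df <- tibble::tibble(
    x = rep(raster_x_centers(h), each = h$n_rows),
    y = rep(raster_y_centers(h), times = h$n_cols),
    domain = as.vector(object$domain),
    habitat = as.vector(object$mask)
  )
  df <- df[df$domain, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                   fill = .data$habitat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85", `TRUE` = "forestgreen"),
                               name = "habitat") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = sprintf("Area of Habitat (%s): %.1f km2",
                                  object$domain_label, object$area_km2))
}

#' @describeIn scope_kba Potential-KBA habitat with the scanning grid's
#'   triggering cells outlined.
#' @param object A `kba_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.kba_result <- function(object, ...) {
  h <- object$header
  idx <- which(object$kba_mask)
  ij <- arrayInd(idx, dim(object$kba_mask))
  df <- tibble::tibble(x = h$origin_x + (ij[, 2] - 0.5) * h$cell_size,
                       y = h$origin_y + (ij[, 1] - 0.5) * h$cell_size)
  g <- object$grid
  cells <- object$cell_fractions[object$cell_fractions$triggers_a1 |
                                   object$cell_fractions$triggers_b1, ]
  boxes <- tibble::tibble(
    xmin = g$origin_x + cells$cell_i * g$cell_size,
    xmax = g$origin_x + (cells$cell_i + 1) * g$cell_size,
    ymin = g$origin_y + cells$cell_j * g$cell_size,
    ymax = g$origin_y + (cells$cell_j + 1) * g$cell_size
  )
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000),
                         fill = "darkorange") +
    ggplot2::geom_rect(data = boxes,
                       ggplot2::aes(xmin = .data$xmin / 1000, xmax = .data$xmax / 1000,
                                    ymin = .data$ymin / 1000, ymax = .data$ymax / 1000),
                       fill = NA, colour = "grey30", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = sprintf("Potential KBAs: %.1f km2 (%.1f%% of AOH)",
                                  object$total_area_km2, object$pct_of_aoh))
}
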