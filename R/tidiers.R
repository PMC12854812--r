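#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a restoration scenario into per-pixel records
#'
#' One row per *selected* pixel: grid position, cell-center coordinates,
#' habitat community code, cost, and the iteration in which the pixel
#' was chosen. Use `selected_only = FALSE` for all analyzable pixels
#' (iteration 0 = not selected).
#'
#' @param x A `restoration_scenario`.
#' @param selected_only Keep only selected pixels (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `habitat`,
#'   `cost_usd_per_ha`, `iteration`.
#' @method tidy restoration_scenario
#' @export
tidy.restoration_scenario <- function(x, selected_only = TRUE, ...) {
  out <- surface_tbl(x$selection, drop_na = TRUE)
  names(out)[names(out) == "value"] <- "iteration"
  out$habitat <- as.integer(x$available$values[cbind(out$row, out$col)])
  out$cost_usd_per_ha <- as.numeric(x$cost$values[cbind(out$row, out$col)])
  if (selected_only) out <- out[out$iteration > 0, ]
  tibble::as_tibble(out[, c("row", "col", "x", "y", "habitat",
                            "cost_usd_per_ha", "iteration")])
}

#' One-row summary of a restoration scenario
#'
#' @param x A `restoration_scenario`.
#' @param ... Unused.
#' @return A tibble with the scenario label, configuration highlights,
#'   selection size and area, cost totals, and the summed objective.
#' @method glance restoration_scenario
#' @export
glance.restoration_scenario <- function(x, ...) {
  costs <- x$report$costs
  tibble::tibble(
    label = x$config$label,
    dispersal_mode = x$config$dispersal_mode,
    use_suitability = x$config$use_suitability,
    z = x$config$z,
    min_habitat_fraction = x$config$min_habitat_fraction_total,
    n_iterations = x$config$n_iterations,
    n_available = x$n_total,
    n_selected = costs$n_selected,
    area_ha = costs$area_ha,
    area_km2 = costs$area_ha / 100,
    total_cost_usd = costs$total_cost_usd,
    avg_cost_usd_ha = costs$avg_cost_usd_ha,
    avg_cost_usd_ha_display = costs$avg_cost_usd_ha_display,
    objective = sum(x$iterations$objective)
  )
}

#' Plot a raster surface
#'
#' Cell-center tile map of a surface; categorical codes become a
#' discrete fill, continuous values a gradient. Nodata cells are
#' omitted.
#'
#' @param object An `rp_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rp_surface
#' @export
autoplot.rp_surface <- function(object, ...) {
  d <- surface_tbl(object, drop_na = TRUE)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
  if (inherits(object, "rp_categorical")) {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::labs(fill = "code")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::labs(fill = object$units %||% "value")
  }
}

#' Plot the selection map of a scenario
#'
#' Analyzable-but-unselected pixels in grey, selected pixels colored by
#' the iteration in which they were chosen.
#'
#' @param object A `restoration_scenario`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot restoration_scenario
#' @export
autoplot.restoration_scenario <- function(object, ...) {
  d <- tidy(object, selected_only = FALSE)
  d$iteration <- factor(d$iteration)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$iteration)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c("0" = "grey85",
                 stats::setNames(grDevices::hcl.colors(object$config$n_iterations, "Viridis"),
                                 seq_len(object$config$n_iterations))),
      name = "iteration"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$config$label, x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
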