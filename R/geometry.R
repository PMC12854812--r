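#' Range geometry: a species' current or historical extent
#'
#' A range is a planar multipolygon in the analysis CRS, stored as a list
#' of simple, pairwise-disjoint rings (two-column matrices of x, y vertex
#' coordinates, meters; open rings, no repeated closing vertex).
#' Interior rings (holes) are not supported, so the planar area is the
#' sum of ring areas and is exact and resolution independent.
#'
#' @param rings List of numeric matrices with columns x, y (>= 3 vertices
#'   each), or a single matrix.
#' @param role `"current"` or `"historical"`.
#' @return An object of class `rp_range`.
#' @examples
#' sq <- range_geometry(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
#' range_area_km2(sq) # 1
#' @export
range_geometry <- function(rings, role = c("current", "historical")) {
  role <- match.arg(role)
  if (is.matrix(rings)) rings <- list(rings)
  if (length(rings) == 0) stop("range geometry must contain at least one ring")
  rings <- lapply(rings, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 3) stop("each ring needs >= 3 (x, y) vertices")
    if (!all(is.finite(m))) stop("ring vertices must be finite")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  })
  structure(list(rings = rings, role = role), class = "rp_range")
}

#' @export
print.rp_range <- function(x, ...) {
  cat(sprintf("<rp_range: %s> %d ring(s), %.4g km2\n",
              x$role, length(x$rings), range_area_km2(x)))
  invisible(x)
}

#' Planar area of a range geometry
#'
#' Exact polygon (shoelace) area summed over rings, in square kilometers.
#' This is the quantity used for the species-area terms `A_c` and `A_O`:
#' planar vector area, not rasterized cell counting, so it does not
#' depend on analysis resolution.
#'
#' @param range An [range_geometry()].
#' @return Area in km^2.
#' @export
range_area_km2 <- function(range) {
  stopifnot(inherits(range, "rp_range"))
  a_m2 <- sum(vapply(range$rings,
                     function(m) abs(pracma::polyarea(m[, 1], m[, 2])),
                     numeric(1)))
  a_m2 / 1e6
}

#' Rasterize a range onto a grid
#'
#' Cell-center rule: a cell gets code 1 iff its center lies inside (or on
#' the boundary of) any ring of the range; otherwise 0. As the cell size
#' shrinks, `sum(cells) * pixel_area` converges to the polygon area.
#'
#' @param range A [range_geometry()].
#' @param grid An [rp_grid()].
#' @return Binary `rp_categorical` surface (0/1, no nodata).
#' @export
rasterize_range <- function(range, grid) {
  stopifnot(inherits(range, "rp_range"), inherits(grid, "rp_grid"))
  cc <- cell_centers(grid)
  px <- rep(cc$x, each = grid$n_rows)
  py <- rep(cc$y, times = grid$n_cols)
  inside <- rep(FALSE, length(px))
  for (ring in range$rings) {
    # bbox pre-filter keeps the point-in-polygon test to candidate cells
    cand <- which(!inside &
                    px >= min(ring[, 1]) & px <= max(ring[, 1]) &
                    py >= min(ring[, 2]) & py <= max(ring[, 2]))
    if (length(cand) == 0) next
    hit <- pracma::inpolygon(px[cand], py[cand], ring[, 1], ring[, 2],
                             boundary = TRUE)
    inside[cand[hit]] <- TRUE
  }
  categorical_surface(grid, matrix(as.integer(inside), grid$n_rows, grid$n_cols))
}

#' Distance-to-range surface and dispersal buffer mask
#'
#' `range_distance_surface()` computes, for every cell, the Euclidean
#' distance (meters, center to center) from the cell to the nearest cell
#' of the rasterized range, via an exact Euclidean distance transform.
#' `dispersal_buffer_mask()` thresholds it at a dispersal distance:
#' cells within `distance_km` of the range (including the range itself)
#' get 1, all others 0. Buffering is performed in raster space at
#' analysis resolution; it is exactly monotone in the distance
#' (a larger buffer always contains a smaller one) and always contains
#' the rasterized range.
#'
#' @param range A [range_geometry()] (typically the current range).
#' @param grid An [rp_grid()].
#' @param distance_km Dispersal distance in kilometers, >= 0.
#' @return `range_distance_surface`: continuous surface in meters.
#'   `dispersal_buffer_mask`: binary `rp_categorical` surface.
#' @export
range_distance_surface <- function(range, grid) {
  mask <- rasterize_range(range, grid)
  m <- mask$values
  if (all(m == 0L)) {
    warning("range covers no cell centers on this grid; distances are infinite")
    return(continuous_surface(grid, matrix(Inf, grid$n_rows, grid$n_cols),
                              units = "m"))
  }
  # distmap: per-pixel distance to the nearest background (0) pixel.
  # Feeding the complement gives distance to the nearest range cell.
  d_px <- EBImage::distmap(matrix(1 - m, grid$n_rows, grid$n_cols),
                           metric = "euclidean")
  continuous_surface(grid, matrix(as.numeric(d_px), grid$n_rows, grid$n_cols) * grid$cell_size,
                     units = "m")
}

#' @rdname range_distance_surface
#' @export
dispersal_buffer_mask <- function(range, distance_km, grid) {
  if (length(distance_km) != 1 || is.na(distance_km) || distance_km < 0) {
    stop("dispersal distance must be a single value >= 0")
  }
  d <- range_distance_surface(range, grid)
  categorical_surface(grid, matrix(as.integer(d$values <= distance_km * 1000),
                                   grid$n_rows, grid$n_cols))
}
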