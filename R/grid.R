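#' Define an analysis grid
#'
#' A grid describes the georeferencing of every raster surface in an
#' analysis: dimensions, lower-left corner, square cell size, and the
#' identifier of a *projected equal-area* CRS. All surfaces in one
#' [landscape_bundle()] must share a bit-identical grid, so per-pixel area
#' is a single constant for the whole analysis.
#'
#' Geographic (longitude/latitude) grids are rejected rather than silently
#' reprojected: cell areas would not be constant and every area-based
#' quantity downstream (species-area terms, area caps, habitat minima)
#' would be wrong.
#'
#' @param n_rows,n_cols Grid dimensions (rows run north to south).
#' @param cell_size Cell edge length in meters (cells are square).
#' @param origin_x,origin_y Coordinates of the lower-left (south-west)
#'   corner in meters.
#' @param crs_id Free-text identifier of the projected equal-area CRS,
#'   e.g. `"EPSG:5070"`. Identifiers containing `"4326"` or `"longlat"`
#'   are rejected.
#' @return An object of class `rp_grid`.
#' @examples
#' g <- rp_grid(10, 10, cell_size = 960)
#' pixel_area_ha(g) # 92.16
#' @export
rp_grid <- function(n_rows, n_cols, cell_size,
                    origin_x = 0, origin_y = 0,
                    crs_id = "local-albers") {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  if (n_rows < 1 || n_cols < 1) stop("grid must have at least one row and column")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (grepl("4326|longlat|wgs *84", tolower(crs_id))) {
    stop("geographic CRS '", crs_id, "' rejected: analysis requires a projected equal-area CRS")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_id = as.character(crs_id)),
    class = "rp_grid"
  )
}

#' @export
print.rp_grid <- function(x, ...) {
  cat(sprintf("<rp_grid> %d x %d cells, %g m resolution, origin (%g, %g), CRS %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

grids_identical <- function(a, b) {
  identical(unclass(a), unclass(b))
}

stop_if_grid_mismatch <- function(a, b, what = "surfaces") {
  if (!grids_identical(a, b)) {
    stop("alignment error: ", what, " are not on identical grids", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pixel area of a grid
#'
#' @param grid An [rp_grid()].
#' @return Area of one cell, in hectares (`pixel_area_ha`) or square
#'   kilometers (`pixel_area_km2`).
#' @examples
#' pixel_area_ha(rp_grid(1, 1, cell_size = 480)) # 23.04
#' @export
pixel_area_ha <- function(grid) {
  stopifnot(inherits(grid, "rp_grid"))
  grid$cell_size^2 / 1e4
}

#' @rdname pixel_area_ha
#' @export
pixel_area_km2 <- function(grid) {
  stopifnot(inherits(grid, "rp_grid"))
  grid$cell_size^2 / 1e6
}

# Cell-center coordinates. Row 1 is the northernmost row (matrix layout
# matches the on-disk ASCII-grid layout); origin is the lower-left corner.
cell_centers <- function(grid) {
  x <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  y <- grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
  list(x = x, y = y)
}

new_surface <- function(grid, values, kind, units = NULL) {
  stopifnot(inherits(grid, "rp_grid"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("values matrix does not match grid dimensions")
  }
  structure(
    list(grid = grid, values = values, units = units),
    class = c(paste0("rp_", kind), "rp_surface")
  )
}

#' Construct raster surfaces on a grid
#'
#' A categorical surface holds one integer class code per cell (habitat
#' community, land-cover class, selection label); a continuous surface
#' holds a real value per cell with a units string (e.g. `"USD/ha"`,
#' `"ln USD/ha"`, or a dimensionless suitability in `[0, 1]`). `NA` is the
#' nodata value in memory.
#'
#' @param grid An [rp_grid()].
#' @param values Matrix of `grid$n_rows` x `grid$n_cols` values; integer
#'   codes (categorical) or numeric (continuous). `NA` marks nodata.
#' @param units Units string recorded verbatim (continuous only).
#' @return An `rp_categorical` / `rp_continuous` object (both inherit
#'   `rp_surface`).
#' @export
categorical_surface <- function(grid, values) {
  if (is.numeric(values) && !is.integer(values)) {
    if (any(values[!is.na(values)] != round(values[!is.na(values)]))) {
      stop("categorical surface requires integer codes")
    }
    storage.mode(values) <- "integer"
  }
  new_surface(grid, values, "categorical")
}

#' @rdname categorical_surface
#' @export
continuous_surface <- function(grid, values, units = "") {
  storage.mode(values) <- "double"
  new_surface(grid, values, "continuous", units = units)
}

#' @export
print.rp_surface <- function(x, ...) {
  kind <- if (inherits(x, "rp_categorical")) "categorical" else "continuous"
  n_valid <- sum(!is.na(x$values))
  cat(sprintf("<rp_surface: %s> %d x %d, %d valid cells",
              kind, x$grid$n_rows, x$grid$n_cols, n_valid))
  if (!is.null(x$units) && nzchar(x$units)) cat(" [", x$units, "]", sep = "")
  cat("\n")
  if (inherits(x, "rp_categorical")) {
    tab <- table(x$values)
    cat("  codes:", paste(names(tab), collapse = ", "), "\n")
  } else if (n_valid > 0) {
    cat(sprintf("  range: %g .. %g\n", min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}

#' Surface values as a tibble of cell records
#'
#' Long-format view used by the plotting methods and convenient for dplyr
#' work: one row per cell with row/col indices, cell-center coordinates,
#' and the cell value.
#'
#' @param x An `rp_surface`.
#' @param drop_na Drop nodata cells (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
surface_tbl <- function(x, drop_na = TRUE, ...) {
  stopifnot(inherits(x, "rp_surface"))
  cc <- cell_centers(x$grid)
  out <- tibble::tibble(
    row = rep(seq_len(x$grid$n_rows), times = x$grid$n_cols),
    col = rep(seq_len(x$grid$n_cols), each = x$grid$n_rows),
    value = as.vector(x$values)
  )
  out$x <- cc$x[out$col]
  out$y <- cc$y[out$row]
  out <- out[, c("row", "col", "x", "y", "value")]
  if (drop_na) out <- out[!is.na(out$value), ]
  tibble::as_tibble(out)
}

#' @method as_tibble rp_surface
#' @export
as_tibble.rp_surface <- function(x, ...) surface_tbl(x, ...)
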