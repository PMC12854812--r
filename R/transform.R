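#' Convert a log-scale land-value surface to dollars
#'
#' Parcel-level fair-market land-value layers are commonly distributed
#' in natural-log USD per hectare. This exponentiates each
#' cell to USD/ha. Nodata propagates; any real value is a valid log
#' price.
#'
#' @param cost_ln Continuous surface with units `"ln USD/ha"`.
#' @return Continuous surface in `"USD/ha"`.
#' @examples
#' g <- rp_grid(1, 2, cell_size = 100)
#' s <- continuous_surface(g, matrix(c(0, log(2500)), 1), units = "ln USD/ha")
#' exp_transform_cost(s)$values # 1, 2500
#' @export
exp_transform_cost <- function(cost_ln) {
  stopifnot(inherits(cost_ln, "rp_continuous"))
  if (!identical(cost_ln$units, "ln USD/ha")) {
    stop("exp_transform_cost expects units 'ln USD/ha', got '", cost_ln$units, "'")
  }
  continuous_surface(cost_ln$grid, exp(cost_ln$values), units = "USD/ha")
}

#' Coarsen a surface to a lower resolution
#'
#' Aggregates `factor` x `factor` blocks of cells into one coarse cell:
#' the mean of non-nodata fine cells for continuous surfaces, the modal
#' code for categorical surfaces with ties broken deterministically
#' toward the lowest code. All-nodata blocks stay nodata. When `factor`
#' does not divide the dimensions, trailing partial blocks (south and
#' east edges) are aggregated over the cells they do contain; the coarse
#' grid keeps the original top-left corner, so the lower-left origin
#' shifts south by the padded amount.
#'
#' @param surface An `rp_surface`.
#' @param factor Integer aggregation factor, at least 2.
#' @return A surface of the same kind on the coarsened grid
#'   (`cell_size * factor`).
#' @examples
#' g <- rp_grid(2, 2, cell_size = 480)
#' s <- continuous_surface(g, matrix(c(100, 300, 200, 400), 2, 2), "USD/ha")
#' coarsen(s, 2)$values # 250
#' @export
coarsen <- function(surface, factor) {
  stopifnot(inherits(surface, "rp_surface"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2) stop("coarsening factor must be an integer >= 2")
  g <- surface$grid
  nr_c <- ceiling(g$n_rows / factor)
  nc_c <- ceiling(g$n_cols / factor)
  v <- surface$values
  categorical <- inherits(surface, "rp_categorical")

  agg <- matrix(NA_real_, nr_c, nc_c)
  for (i in seq_len(nr_c)) {
    rows <- ((i - 1) * factor + 1):min(i * factor, g$n_rows)
    for (j in seq_len(nc_c)) {
      cols <- ((j - 1) * factor + 1):min(j * factor, g$n_cols)
      block <- v[rows, cols]
      block <- block[!is.na(block)]
      if (length(block) == 0) next
      agg[i, j] <- if (categorical) modal_code(block) else mean(block)
    }
  }
  # Row 1 (north edge) stays anchored; padded partial rows extend the
  # coarse grid southwards past the original origin.
  top_y <- g$origin_y + g$n_rows * g$cell_size
  new_grid <- rp_grid(nr_c, nc_c, cell_size = g$cell_size * factor,
                      origin_x = g$origin_x,
                      origin_y = top_y - nr_c * factor * g$cell_size,
                      crs_id = g$crs_id)
  if (categorical) {
    categorical_surface(new_grid, agg)
  } else {
    continuous_surface(new_grid, agg, units = surface$units)
  }
}

# Modal value of an integer vector; ties broken toward the lowest code.
modal_code <- function(codes) {
  tab <- table(codes)
  best <- names(tab)[tab == max(tab)]
  min(as.numeric(best))
}
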