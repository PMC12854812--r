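#' Read and write raster surfaces as Esri ASCII grids
#'
#' The on-disk raster format is the plain-text Esri ASCII grid (`.asc`):
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of whitespace-separated
#' values, northernmost row first. The format carries no CRS, so the CRS
#' identifier is supplied at read time (a convention shared with the
#' side-car `.prj` files most GIS tools emit).
#'
#' `read_categorical()` enforces integer codes: a file with fractional
#' values is a format error, not silently truncated.
#'
#' @param path Path to a `.asc` file.
#' @param units Units string recorded verbatim on the result
#'   (continuous only).
#' @param crs_id CRS identifier to stamp on the grid.
#' @return An `rp_categorical` / `rp_continuous` surface.
#' @examples
#' g <- rp_grid(2, 2, cell_size = 100)
#' s <- categorical_surface(g, matrix(c(1L, 2L, NA, 1L), 2, 2))
#' f <- tempfile(fileext = ".asc")
#' write_surface(s, f)
#' identical(read_categorical(f)$values, s$values)
#' @export
read_categorical <- function(path, crs_id = "local-albers") {
  parsed <- read_ascii_grid(path, crs_id)
  v <- parsed$values
  ok <- !is.na(v)
  if (any(v[ok] != round(v[ok]))) {
    stop("format error: '", path, "' contains non-integer values; not a categorical raster")
  }
  categorical_surface(parsed$grid, v)
}

#' @rdname read_categorical
#' @export
read_continuous <- function(path, units = "", crs_id = "local-albers") {
  parsed <- read_ascii_grid(path, crs_id)
  if (all(is.na(parsed$values))) {
    warning("'", path, "' has no valid cells (all nodata)")
  }
  continuous_surface(parsed$grid, parsed$values, units = units)
}

read_ascii_grid <- function(path, crs_id) {
  if (!file.exists(path)) stop("cannot read raster: no such file '", path, "'")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("format error: '", path, "' is not an Esri ASCII grid")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) stop("format error: bad header line ", i, " in '", path, "'")
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(req %in% names(hdr))) {
    stop("format error: missing header fields in '", path, "'")
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) {
    stop("format error: expected ", nr * nc, " values in '", path, "', found ", length(body))
  }
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  vals[vals == hdr$nodata_value] <- NA
  grid <- rp_grid(nr, nc, cell_size = hdr$cellsize,
                  origin_x = hdr$xllcorner, origin_y = hdr$yllcorner,
                  crs_id = crs_id)
  list(grid = grid, values = vals)
}

#' @rdname read_categorical
#' @param surface Surface to write.
#' @param nodata Sentinel written for `NA` cells.
#' @export
write_surface <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "rp_surface"))
  g <- surface$grid
  hdr <- c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", format(g$origin_x, scientific = FALSE)),
    paste("yllcorner", format(g$origin_y, scientific = FALSE)),
    paste("cellsize", format(g$cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  )
  v <- surface$values
  if (any(!is.na(v) & v == nodata)) {
    stop("a data value collides with the nodata sentinel ", nodata)
  }
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read and write range geometries as GeoJSON
#'
#' Range maps (current or historical species extent) are planar
#' multipolygons in the analysis CRS, stored as GeoJSON
#' `MultiPolygon`/`Polygon` geometries (optionally wrapped in a Feature or
#' FeatureCollection). Rings must be simple and disjoint; interior rings
#' (holes) are not supported and raise an error.
#'
#' @param path Path to a `.geojson` file.
#' @param role `"current"` or `"historical"`.
#' @return A [range_geometry()].
#' @export
read_range_geojson <- function(path, role = c("current", "historical")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("cannot read range: no such file '", path, "'")
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- extract_geometry(gj)
  rings <- geojson_rings(geom)
  range_geometry(rings, role = role)
}

extract_geometry <- function(gj) {
  type <- gj$type
  if (is.null(type)) stop("format error: not GeoJSON")
  if (type == "FeatureCollection") {
    if (length(gj$features) != 1) stop("expected exactly one feature in range GeoJSON")
    return(extract_geometry(gj$features[[1]]))
  }
  if (type == "Feature") return(gj$geometry)
  gj
}

geojson_rings <- function(geom) {
  coords_to_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON closes rings by repeating the first vertex; store open rings
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  if (geom$type == "Polygon") {
    polys <- list(geom$coordinates)
  } else if (geom$type == "MultiPolygon") {
    polys <- geom$coordinates
  } else {
    stop("format error: geometry type '", geom$type, "' is not a (Multi)Polygon")
  }
  rings <- list()
  for (poly in polys) {
    if (length(poly) > 1) stop("interior rings (holes) are not supported")
    rings[[length(rings) + 1]] <- coords_to_mat(poly[[1]])
  }
  rings
}

#' @rdname read_range_geojson
#' @param range A [range_geometry()] to write.
#' @export
write_range_geojson <- function(range, path) {
  stopifnot(inherits(range, "rp_range"))
  close_ring <- function(m) rbind(m, m[1, , drop = FALSE])
  polys <- lapply(range$rings, function(m) {
    ring <- apply(close_ring(m), 1, function(p) list(p[[1]], p[[2]]), simplify = FALSE)
    list(ring)
  })
  gj <- list(type = "MultiPolygon", coordinates = polys)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
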