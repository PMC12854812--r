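#' Write and read a landscape bundle as a directory of text files
#'
#' The on-disk bundle layout consumed and produced by the command-line
#' tool: Esri ASCII grids for every surface, GeoJSON ranges, a species
#' CSV, and a `bundle.json` manifest recording cost units, the CRS
#' identifier, the package version, and an MD5 checksum per file
#' (re-running any stage on an unchanged manifest reproduces identical
#' outputs).
#'
#' ```
#' dir/
#'   habitat.asc  landcover.asc  cost.asc
#'   suitability/<species>.asc      (if present)
#'   ranges/<species>_{current,historical}.geojson
#'   species.csv
#'   bundle.json
#' ```
#'
#' @param bundle A [landscape_bundle()].
#' @param profiles List of [species_profile()] objects.
#' @param dir Target / source directory.
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()`
#'   returns `list(bundle, profiles)`.
#' @export
write_bundle <- function(bundle, profiles, dir) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  profiles <- as_profile_list(profiles)
  dir.create(file.path(dir, "ranges"), recursive = TRUE, showWarnings = FALSE)
  write_surface(bundle$habitat, file.path(dir, "habitat.asc"))
  write_surface(bundle$landcover, file.path(dir, "landcover.asc"))
  write_surface(bundle$cost, file.path(dir, "cost.asc"))
  if (!is.null(bundle$suitability)) {
    dir.create(file.path(dir, "suitability"), showWarnings = FALSE)
    for (nm in names(bundle$suitability)) {
      write_surface(bundle$suitability[[nm]], file.path(dir, "suitability", paste0(nm, ".asc")))
    }
  }
  rows <- lapply(profiles, function(p) {
    cur <- file.path("ranges", paste0(p$name, "_current.geojson"))
    his <- file.path("ranges", paste0(p$name, "_historical.geojson"))
    write_range_geojson(p$current_range, file.path(dir, cur))
    write_range_geojson(p$historical_range, file.path(dir, his))
    tibble::tibble(name = p$name,
                   preferred_habitat_codes = paste(p$preferred_habitat_codes, collapse = ";"),
                   dispersal_km = p$dispersal_km, z = p$z, weight = p$weight,
                   current_range_file = cur, historical_range_file = his)
  })
  readr::write_csv(dplyr::bind_rows(rows), file.path(dir, "species.csv"))
  files <- setdiff(list.files(dir, recursive = TRUE), "bundle.json")
  manifest <- list(
    format = "sarplan-bundle-1",
    package_version = as.character(utils::packageVersion("sarplan")),
    cost_units = bundle$cost$units,
    crs_id = bundle$grid$crs_id,
    created = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(file.path(dir, files))) |>
      stats::setNames(files)
  )
  jsonlite::write_json(manifest, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  mf_path <- file.path(dir, "bundle.json")
  if (!file.exists(mf_path)) stop("'", dir, "' is not a bundle directory (no bundle.json)")
  mf <- jsonlite::read_json(mf_path)
  crs <- mf$crs_id %||% "local-albers"
  habitat <- read_categorical(file.path(dir, "habitat.asc"), crs_id = crs)
  landcover <- read_categorical(file.path(dir, "landcover.asc"), crs_id = crs)
  cost <- read_continuous(file.path(dir, "cost.asc"),
                          units = mf$cost_units %||% "ln USD/ha", crs_id = crs)
  suit_dir <- file.path(dir, "suitability")
  suitability <- NULL
  if (dir.exists(suit_dir)) {
    fls <- list.files(suit_dir, pattern = "\\.asc$", full.names = TRUE)
    suitability <- lapply(fls, read_continuous, units = "suitability", crs_id = crs)
    names(suitability) <- sub("\\.asc$", "", basename(fls))
  }
  profiles <- load_species_table(file.path(dir, "species.csv"),
                                 habitat_codes = sort(unique(habitat$values[!is.na(habitat$values)])))
  if (!is.null(suitability)) {
    # surfaces are keyed by species name; present them in table order
    nm <- vapply(profiles, `[[`, character(1), "name")
    suitability <- suitability[c(intersect(nm, names(suitability)),
                                 setdiff(names(suitability), nm))]
  }
  list(bundle = landscape_bundle(habitat, landcover, cost, suitability),
       profiles = profiles)
}
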