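#' Species profile
#'
#' Parameterization of one indicator species: the habitat community
#' classes it depends on, its dispersal distance, its species-area
#' exponent and optional aggregation weight, and its current and
#' historical range geometries (from which the SAR areas `A_c` and `A_O`
#' are measured as planar polygon areas).
#'
#' @param name Species name (unique within an analysis).
#' @param preferred_habitat_codes Integer habitat class codes (non-empty).
#' @param dispersal_km Dispersal distance in kilometers (>= 0).
#' @param z SAR exponent in (0, 1).
#' @param weight Nonnegative aggregation weight `w_j` (default 1).
#' @param current_range,historical_range [range_geometry()] objects with
#'   matching roles.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name, preferred_habitat_codes, dispersal_km,
                            current_range, historical_range,
                            z = 0.25, weight = 1) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("species name must be a non-empty string")
  }
  preferred_habitat_codes <- unique(as.integer(preferred_habitat_codes))
  if (length(preferred_habitat_codes) == 0 || any(is.na(preferred_habitat_codes))) {
    stop("species '", name, "': preferred_habitat_codes must be non-empty integers")
  }
  if (length(dispersal_km) != 1 || is.na(dispersal_km) || dispersal_km < 0) {
    stop("species '", name, "': dispersal_km must be >= 0")
  }
  if (length(z) != 1 || is.na(z) || z <= 0 || z >= 1) {
    stop("species '", name, "': z must lie in (0, 1)")
  }
  if (length(weight) != 1 || is.na(weight) || weight < 0) {
    stop("species '", name, "': weight must be >= 0")
  }
  stopifnot(inherits(current_range, "rp_range"), inherits(historical_range, "rp_range"))
  structure(
    list(name = name,
         preferred_habitat_codes = preferred_habitat_codes,
         dispersal_km = as.numeric(dispersal_km),
         z = as.numeric(z), weight = as.numeric(weight),
         current_range = current_range,
         historical_range = historical_range),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s | habitat {%s} | dispersal %g km | z %g | w %g\n",
              x$name, paste(x$preferred_habitat_codes, collapse = ","),
              x$dispersal_km, x$z, x$weight))
  invisible(x)
}

#' Initial SAR state of a set of species
#'
#' Measures each species' current and original habitat area (km^2,
#' planar polygon area of its range geometries) and returns the tibble
#' of SAR states the iterative optimization updates: `area_current_km2`
#' grows as pixels are restored, `area_original_km2` is fixed.
#'
#' @param profiles List of [species_profile()] objects.
#' @return Tibble with columns `species`, `area_current_km2`,
#'   `area_original_km2`.
#' @export
species_states <- function(profiles) {
  profiles <- as_profile_list(profiles)
  tibble::tibble(
    species = vapply(profiles, function(p) p$name, character(1)),
    area_current_km2 = vapply(profiles, function(p) range_area_km2(p$current_range), numeric(1)),
    area_original_km2 = vapply(profiles, function(p) range_area_km2(p$historical_range), numeric(1))
  )
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "species_profile")))
  nm <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate species name: ", nm[duplicated(nm)][1])
  profiles
}

#' Load a species parameter table
#'
#' Reads a CSV with one row per species and columns `name`,
#' `preferred_habitat_codes` (semicolon-separated integer codes),
#' `dispersal_km`, `z`, `weight`, `current_range_file`,
#' `historical_range_file` (GeoJSON paths, resolved relative to the CSV
#' unless absolute). Every row is validated against the profile
#' invariants; errors name the offending row.
#'
#' @param path CSV file path.
#' @param habitat_codes Optional integer vector of declared habitat
#'   classes; any preferred code outside it is an error.
#' @return List of [species_profile()] objects.
#' @export
load_species_table <- function(path, habitat_codes = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("name", "preferred_habitat_codes", "dispersal_km", "z", "weight",
           "current_range_file", "historical_range_file")
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    stop("species table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  base_dir <- dirname(path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  profiles <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    codes <- suppressWarnings(as.integer(strsplit(as.character(row$preferred_habitat_codes), ";")[[1]]))
    if (any(is.na(codes))) stop("row ", i, " ('", row$name, "'): unparsable habitat codes")
    if (!is.null(habitat_codes) && !all(codes %in% habitat_codes)) {
      stop("row ", i, " ('", row$name, "'): unknown habitat code ",
           paste(setdiff(codes, habitat_codes), collapse = ","))
    }
    profiles[[i]] <- tryCatch(
      species_profile(
        name = as.character(row$name),
        preferred_habitat_codes = codes,
        dispersal_km = row$dispersal_km,
        z = row$z, weight = row$weight,
        current_range = read_range_geojson(resolve(row$current_range_file), "current"),
        historical_range = read_range_geojson(resolve(row$historical_range_file), "historical")
      ),
      error = function(e) stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
    )
  }
  as_profile_list(profiles)
}
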