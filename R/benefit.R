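#' Area available for restoration
#'
#' Masks the historical habitat-community map to the cells whose current
#' land cover is restorable (by default NLCD classes 81 pasture/hay and
#' 82 cultivated crops). A cell keeps its habitat community code iff its
#' land cover is restorable and it carries a habitat code; every other
#' cell becomes nodata. The result defines both the candidate pixel set
#' and the habitat-type membership `G_a` used by the optimizer.
#'
#' @param habitat Categorical surface of historical habitat communities.
#' @param landcover Categorical surface of current land cover on the
#'   same grid.
#' @param restorable_codes Land-cover codes considered restorable
#'   (default `c(81, 82)`).
#' @return Categorical surface (class `available_area`, inheriting
#'   `rp_categorical`) with habitat codes on restorable cells.
#' @export
compute_available_area <- function(habitat, landcover, restorable_codes = c(81L, 82L)) {
  stopifnot(inherits(habitat, "rp_categorical"), inherits(landcover, "rp_categorical"))
  stop_if_grid_mismatch(habitat$grid, landcover$grid, "habitat and landcover")
  keep <- !is.na(habitat$values) & !is.na(landcover$values) &
    landcover$values %in% as.integer(restorable_codes)
  v <- habitat$values
  v[!keep] <- NA_integer_
  if (!any(keep)) warning("no restorable cells: available area is empty")
  out <- categorical_surface(habitat$grid, v)
  class(out) <- c("available_area", class(out))
  attr(out, "restorable_codes") <- as.integer(restorable_codes)
  out
}

#' Dispersal weight surface for one species
#'
#' Implements the three dispersal scenarios. The current range is
#' buffered by the species' dispersal distance (Euclidean, in the
#' equal-area CRS at grid resolution); cells inside the buffer always
#' get weight 1, cells outside get the mode's outside weight:
#'
#' * `"none"` - 1 (distance ignored; the buffer is not even computed),
#' * `"intermediate"` - 0.5 (colonization possible but slower),
#' * `"natural"` - 0 (only naturally reachable cells benefit).
#'
#' @param profile A [species_profile()].
#' @param mode One of `"none"`, `"intermediate"`, `"natural"`.
#' @param grid An [rp_grid()].
#' @return Continuous surface of weights in `{0, 0.5, 1}`.
#' @export
dispersal_weight_surface <- function(profile, mode = c("none", "intermediate", "natural"),
                                     grid) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "species_profile"), inherits(grid, "rp_grid"))
  if (mode == "none") {
    return(continuous_surface(grid, matrix(1, grid$n_rows, grid$n_cols), units = ""))
  }
  outside <- if (mode == "intermediate") 0.5 else 0
  buf <- dispersal_buffer_mask(profile$current_range, profile$dispersal_km, grid)
  w <- ifelse(buf$values == 1L, 1, outside)
  continuous_surface(grid, matrix(w, grid$n_rows, grid$n_cols), units = "")
}

# Eligibility mask: historical range (cell-center rasterization) AND
# preferred habitat AND available. Static across iterations, so callers
# that loop (run_scenario) precompute it once.
species_eligibility <- function(profile, available) {
  stopifnot(inherits(available, "available_area"))
  hist_mask <- rasterize_range(profile$historical_range, available$grid)$values == 1L
  hist_mask & !is.na(available$values) &
    available$values %in% profile$preferred_habitat_codes
}

#' Per-species restoration benefit surface
#'
#' The benefit of restoring pixel `x_i` for species `j` is
#' `b_ij = c_ij * (r0_j - r1_j)`, the reduction in SAR extinction risk
#' from adding one pixel of habitat, weighted by climate suitability
#' `c_ij` and the dispersal weight. A cell is eligible iff it lies in
#' the species' historical range, carries one of its preferred habitat
#' codes, and is available for restoration; ineligible cells get exactly
#' 0. The risk-reduction factor uses the species' *current* state, so it
#' is spatially constant within one optimization iteration and shrinks
#' between iterations as `A_c` grows.
#'
#' @param profile A [species_profile()].
#' @param state One row of a [species_states()] tibble (or a list) with
#'   `area_current_km2` and `area_original_km2`.
#' @param available An `available_area` surface.
#' @param dispersal_weights Continuous weight surface from
#'   [dispersal_weight_surface()], or `NULL` for uniform 1.
#' @param suitability Continuous suitability surface in `[0, 1]`, or
#'   `NULL` for uniform 1 (no climate weighting). Values outside
#'   `[0, 1]` by <= 1e-6 are clamped; larger excursions are errors.
#' @param z SAR exponent; defaults to the profile's.
#' @param eligibility Optional precomputed logical matrix from callers
#'   that loop; when `NULL` it is derived from the profile.
#' @return Continuous surface of `b_ij` values (class
#'   `species_benefit`), 0 outside the eligible set.
#' @export
species_benefit_surface <- function(profile, state, available,
                                    dispersal_weights = NULL,
                                    suitability = NULL,
                                    z = profile$z,
                                    eligibility = NULL) {
  stopifnot(inherits(profile, "species_profile"), inherits(available, "available_area"))
  grid <- available$grid
  if (is.null(eligibility)) eligibility <- species_eligibility(profile, available)

  w <- if (is.null(dispersal_weights)) 1 else {
    stop_if_grid_mismatch(grid, dispersal_weights$grid, "available area and dispersal weights")
    dispersal_weights$values
  }
  s <- if (is.null(suitability)) 1 else {
    stop_if_grid_mismatch(grid, suitability$grid, "available area and suitability")
    validate_suitability(suitability$values)
  }
  rr <- risk_reduction(state$area_current_km2, state$area_original_km2,
                       pixel_area_km2(grid), z)
  b <- matrix(0, grid$n_rows, grid$n_cols)
  b[eligibility] <- (rr * w * s * eligibility)[eligibility]
  out <- continuous_surface(grid, b, units = "risk reduction")
  attr(out, "species") <- profile$name
  class(out) <- c("species_benefit", class(out))
  out
}

validate_suitability <- function(v, tol = 1e-6) {
  bad <- !is.na(v) & (v < -tol | v > 1 + tol)
  if (any(bad)) {
    stop("suitability surface has ", sum(bad), " cell(s) outside [0, 1] by more than ", tol)
  }
  pmin(pmax(v, 0), 1)
}

#' Aggregate species benefits into a total benefit surface
#'
#' Cell-wise weighted sum over species, `B_xi = sum_j w_j * b_ij`.
#' Weights default to each profile's `w_j` of 1; the order of the
#' species list does not affect the result. Cells outside the analyzable
#' set (nodata in the available-area surface) become nodata.
#'
#' @param surfaces List of `species_benefit` surfaces.
#' @param weights Numeric vector of per-species weights (recycled from 1).
#' @param available Optional `available_area` surface; when given, cells
#'   that are not available are set to nodata rather than 0.
#' @return Continuous surface of `B_xi` (class `total_benefit`).
#' @export
aggregate_benefit <- function(surfaces, weights = NULL, available = NULL) {
  if (length(surfaces) == 0) stop("aggregate_benefit needs at least one species surface")
  stopifnot(all(vapply(surfaces, inherits, logical(1), "rp_continuous")))
  grid <- surfaces[[1]]$grid
  for (s in surfaces[-1]) stop_if_grid_mismatch(grid, s$grid, "species benefit surfaces")
  if (is.null(weights)) weights <- rep(1, length(surfaces))
  if (length(weights) == 1) weights <- rep(weights, length(surfaces))
  stopifnot(length(weights) == length(surfaces), all(weights >= 0))
  total <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_along(surfaces)) {
    v <- surfaces[[k]]$values
    v[is.na(v)] <- 0
    total <- total + weights[k] * v
  }
  if (!is.null(available)) total[is.na(available$values)] <- NA_real_
  out <- continuous_surface(grid, total, units = "risk reduction")
  class(out) <- c("total_benefit", class(out))
  out
}
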