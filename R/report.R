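#' Cost accounting for a selection
#'
#' Total acquisition cost (USD) and average cost per hectare over the
#' selected pixels. The display average follows the reporting
#' convention of rounding to the nearest $10 (round-half-to-even, R's
#' `round()`); the returned `avg_cost_usd_ha` is unrounded.
#'
#' @param selection Selection-label surface (`> 0` = selected) or a
#'   `site_selection` / `restoration_scenario` object.
#' @param cost Continuous cost surface in USD/ha (not needed when
#'   `selection` is a `site_selection` or scenario).
#' @return One-row tibble: `n_selected`, `area_ha`, `total_cost_usd`,
#'   `avg_cost_usd_ha`, `avg_cost_usd_ha_display`.
#' @examples
#' # two 92.16-ha pixels at 2000 and 3000 USD/ha
#' g <- rp_grid(1, 2, cell_size = 960)
#' sel <- categorical_surface(g, matrix(c(1L, 1L), 1))
#' cost <- continuous_surface(g, matrix(c(2000, 3000), 1), "USD/ha")
#' cost_summary(sel, cost) # total 460,800; avg 2500
#' @export
cost_summary <- function(selection, cost = NULL) {
  if (inherits(selection, "restoration_scenario")) {
    cost <- selection$cost
    selection <- selection$selection
  }
  if (inherits(selection, "site_selection")) {
    px <- selection$pixels
    area_ha <- selection$n_selected * selection$pixel_area_ha
    total <- selection$total_cost_usd
    n <- selection$n_selected
  } else {
    stopifnot(inherits(selection, "rp_categorical"), inherits(cost, "rp_continuous"))
    stop_if_grid_mismatch(selection$grid, cost$grid, "selection and cost")
    if (!identical(cost$units, "USD/ha")) stop("cost surface must be in USD/ha")
    chosen <- !is.na(selection$values) & selection$values > 0L
    n <- sum(chosen)
    area_ha <- n * pixel_area_ha(selection$grid)
    total <- sum(cost$values[chosen]) * pixel_area_ha(selection$grid)
  }
  if (n == 0) {
    warning("empty selection: costs are zero")
    return(tibble::tibble(n_selected = 0L, area_ha = 0, total_cost_usd = 0,
                          avg_cost_usd_ha = 0, avg_cost_usd_ha_display = 0))
  }
  avg <- total / area_ha
  tibble::tibble(n_selected = as.integer(n), area_ha = area_ha,
                 total_cost_usd = total, avg_cost_usd_ha = avg,
                 avg_cost_usd_ha_display = round_to_nearest_10(avg))
}

round_to_nearest_10 <- function(x) round(x / 10) * 10

#' Average cost per hectare under the scenario reporting convention
#'
#' Published scenario tables report the average restoration cost as the
#' total cost divided by the restored area - the target fraction of the
#' available area - rounded to the nearest $10. This helper applies
#' exactly that convention, e.g. to check a reported table row from its
#' printed total and available area.
#'
#' @param total_cost_usd Total scenario cost in USD.
#' @param available_area_km2 Total area available for restoration, km^2.
#' @param target_fraction Fraction of the available area restored
#'   (default 0.30).
#' @return Average cost in USD/ha, rounded to the nearest $10.
#' @examples
#' scenario_cost_per_ha(4951131120, 21874 + 29311 + 16656) # 2430
#' @export
scenario_cost_per_ha <- function(total_cost_usd, available_area_km2,
                                 target_fraction = 0.30) {
  restored_ha <- target_fraction * available_area_km2 * 100
  round_to_nearest_10(total_cost_usd / restored_ha)
}

#' Restored area by habitat type
#'
#' Counts selected pixels per habitat community code and converts to
#' km^2. The per-code areas always sum exactly to the number of selected
#' pixels times the pixel area.
#'
#' @param selection Selection-label surface or `restoration_scenario`.
#' @param available `available_area` surface giving habitat membership
#'   (not needed for a scenario object).
#' @return Tibble with `habitat`, `n_pixels`, `area_km2` (one row per
#'   habitat code present in the available area, zero rows included).
#' @export
habitat_area_summary <- function(selection, available = NULL) {
  if (inherits(selection, "restoration_scenario")) {
    available <- selection$available
    selection <- selection$selection
  }
  stopifnot(inherits(selection, "rp_categorical"), inherits(available, "available_area"))
  stop_if_grid_mismatch(selection$grid, available$grid, "selection and available area")
  chosen <- !is.na(selection$values) & selection$values > 0L
  codes <- sort(unique(available$values[!is.na(available$values)]))
  n_px <- vapply(codes, function(a) sum(chosen & !is.na(available$values) &
                                          available$values == a), integer(1))
  tibble::tibble(habitat = as.integer(codes), n_pixels = n_px,
                 area_km2 = n_px * pixel_area_km2(selection$grid))
}

#' Per-species extinction-risk improvement
#'
#' Reports, for each species and each exponent in the z sweep, the
#' percentage-point reduction in SAR extinction risk achieved by the
#' scenario: `100 * (r0_before - r0_after)`, where both risks are
#' evaluated at the same `A_O` and z from the pre- and post-scenario
#' current areas.
#'
#' @param states_before,states_after [species_states()] tibbles (the
#'   latter reflecting post-restoration `area_current_km2`), or a
#'   `restoration_scenario` as the first argument.
#' @param z Numeric vector of exponents (default the 0.1 / 0.25 / 0.4
#'   sensitivity sweep).
#' @return Tibble with `species`, `z`, `risk_before`, `risk_after`,
#'   `risk_reduction_pct`.
#' @export
risk_improvement_summary <- function(states_before, states_after = NULL,
                                     z = c(0.1, 0.25, 0.4)) {
  if (inherits(states_before, "restoration_scenario")) {
    sc <- states_before
    states_after <- sc$states_after
    states_before <- sc$states_before
    z <- sort(unique(c(z, sc$config$z)))
  }
  stopifnot(identical(states_before$species, states_after$species))
  if (any(states_after$area_current_km2 < states_before$area_current_km2)) {
    stop("area_current_km2 decreased: restoration cannot remove habitat")
  }
  out <- tidyr::crossing(species = states_before$species, z = z)
  i <- match(out$species, states_before$species)
  out$risk_before <- extinction_risk(states_before$area_current_km2[i],
                                     states_before$area_original_km2[i],
                                     rep(1, nrow(out)) * out$z)
  out$risk_after <- extinction_risk(states_after$area_current_km2[i],
                                    states_after$area_original_km2[i],
                                    rep(1, nrow(out)) * out$z)
  out$risk_reduction_pct <- 100 * (out$risk_before - out$risk_after)
  dplyr::arrange(out, species, z)
}

# Full scenario report: assembled once by run_scenario().
scenario_report <- function(scenario) {
  list(
    costs = cost_summary(scenario),
    habitat_areas = habitat_area_summary(scenario),
    risk = risk_improvement_summary(scenario)
  )
}
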