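#' Scenario configuration
#'
#' Bundles every knob of a restoration-prioritization run. The defaults
#' encode the headline study design: restore 30% of the available area
#' in three iterations of 10% each (so diminishing SAR returns are
#' re-evaluated as habitat accrues), with at least 20% of each habitat
#' type restored cumulatively (0.20 / 3 per iteration, the "0.067"
#' coefficient), dispersal ignored, and z = 0.25.
#'
#' @param dispersal_mode `"none"`, `"intermediate"`, or `"natural"`.
#' @param use_suitability Multiply benefits by the bundle's per-species
#'   climate-suitability surfaces (`FALSE` means `c_ij = 1`).
#' @param z SAR exponent in (0, 1).
#' @param target_fraction Total fraction of the available pixels to
#'   restore across all iterations (default 0.30).
#' @param n_iterations Number of optimization iterations (default 3).
#' @param per_iteration_fraction Fraction restored per iteration; must
#'   satisfy `n_iterations * per_iteration_fraction == target_fraction`.
#' @param min_habitat_fraction_total Cumulative minimum fraction of each
#'   habitat type to restore (0, 0.10, or 0.20 in the study design).
#' @param restorable_codes Land-cover codes treated as restorable.
#' @param resolution_factor Integer >= 1; > 1 coarsens all layers by
#'   that factor before analysis.
#' @param cost_transform_order `"exp_then_coarsen"` (default) converts
#'   ln USD/ha to USD/ha before any coarsening, so coarse costs are
#'   means of dollar values; `"coarsen_then_exp"` averages on the log
#'   scale first (geometric-mean-like behavior).
#' @param a_c_update How restored pixels increment a species' current
#'   area: `"all_eligible"` (default; any restored pixel in the species'
#'   historical range and preferred habitat counts - habitat exists
#'   regardless of colonization speed) or `"within_buffer"` (only pixels
#'   with a positive dispersal weight count).
#' @param budget_usd Optional budget cap; switches the optimizer to
#'   maximizing total benefit under a cost constraint.
#' @param label Optional scenario label used in reports.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(dispersal_mode = c("none", "intermediate", "natural"),
                            use_suitability = FALSE,
                            z = 0.25,
                            target_fraction = 0.30,
                            n_iterations = 3L,
                            per_iteration_fraction = target_fraction / n_iterations,
                            min_habitat_fraction_total = 0.20,
                            restorable_codes = c(81L, 82L),
                            resolution_factor = 1L,
                            cost_transform_order = c("exp_then_coarsen", "coarsen_then_exp"),
                            a_c_update = c("all_eligible", "within_buffer"),
                            budget_usd = NULL,
                            label = NULL) {
  dispersal_mode <- match.arg(dispersal_mode)
  cost_transform_order <- match.arg(cost_transform_order)
  a_c_update <- match.arg(a_c_update)
  stopifnot(z > 0, z < 1, n_iterations >= 1, resolution_factor >= 1)
  fr <- c(target_fraction, per_iteration_fraction, min_habitat_fraction_total)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(n_iterations * per_iteration_fraction - target_fraction) > 1e-9) {
    stop("n_iterations * per_iteration_fraction must equal target_fraction")
  }
  structure(
    list(dispersal_mode = dispersal_mode, use_suitability = use_suitability,
         z = z, target_fraction = target_fraction,
         n_iterations = as.integer(n_iterations),
         per_iteration_fraction = per_iteration_fraction,
         min_habitat_fraction_total = min_habitat_fraction_total,
         restorable_codes = as.integer(restorable_codes),
         resolution_factor = as.integer(resolution_factor),
         cost_transform_order = cost_transform_order,
         a_c_update = a_c_update, budget_usd = budget_usd,
         label = label %||% paste0("dispersal-", dispersal_mode)),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file whose keys match the [scenario_config()]
#'   arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in '", path, "': ", paste(unknown, collapse = ", "))
  }
  do.call(scenario_config, vals)
}

#' Landscape bundle
#'
#' Co-registered input layers for one analysis: historical habitat
#' communities, current land cover, a land-value surface (either
#' `"ln USD/ha"` as distributed or already `"USD/ha"`), and optional
#' per-species climate-suitability surfaces in `[0, 1]`.
#'
#' @param habitat,landcover Categorical surfaces on one grid.
#' @param cost Continuous land-value surface on the same grid.
#' @param suitability Optional named list (by species name) of
#'   continuous surfaces in `[0, 1]`.
#' @return An object of class `landscape_bundle`.
#' @export
landscape_bundle <- function(habitat, landcover, cost, suitability = NULL) {
  stopifnot(inherits(habitat, "rp_categorical"),
            inherits(landcover, "rp_categorical"),
            inherits(cost, "rp_continuous"))
  stop_if_grid_mismatch(habitat$grid, landcover$grid, "habitat and landcover")
  stop_if_grid_mismatch(habitat$grid, cost$grid, "habitat and cost")
  if (!is.null(suitability)) {
    stopifnot(is.list(suitability), !is.null(names(suitability)))
    for (s in suitability) {
      stopifnot(inherits(s, "rp_continuous"))
      stop_if_grid_mismatch(habitat$grid, s$grid, "habitat and suitability")
      validate_suitability(s$values)
    }
  }
  structure(list(habitat = habitat, landcover = landcover, cost = cost,
                 suitability = suitability, grid = habitat$grid),
            class = "landscape_bundle")
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle> %d x %d @ %g m | cost units '%s' | %d suitability layer(s)\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, x$cost$units,
              length(x$suitability)))
  invisible(x)
}

# Resolve the cost layer to USD/ha at analysis resolution, honoring the
# configured transform order, and coarsen the other layers to match.
prepare_bundle <- function(bundle, config) {
  f <- config$resolution_factor
  cost <- bundle$cost
  if (identical(cost$units, "ln USD/ha")) {
    if (f > 1 && config$cost_transform_order == "coarsen_then_exp") {
      cost <- exp_transform_cost(coarsen(cost, f))
    } else {
      cost <- exp_transform_cost(cost)
      if (f > 1) cost <- coarsen(cost, f)
    }
  } else if (f > 1) {
    cost <- coarsen(cost, f)
  }
  habitat <- bundle$habitat; landcover <- bundle$landcover
  suitability <- bundle$suitability
  if (f > 1) {
    habitat <- coarsen(habitat, f)
    landcover <- coarsen(landcover, f)
    if (!is.null(suitability)) suitability <- lapply(suitability, coarsen, factor = f)
  }
  landscape_bundle(habitat, landcover, cost, suitability)
}

#' Run the iterative restoration-prioritization scenario
#'
#' The full pipeline: mask the habitat map to restorable land cover,
#' compute per-species benefit surfaces from the SAR risk reduction
#' (weighted by dispersal and, optionally, climate suitability),
#' aggregate across species, and select pixels by exact constrained
#' optimization - repeated for `n_iterations`, adding each iteration's
#' restored pixels to every applicable species' current habitat area so
#' that later iterations see the diminished marginal benefit.
#'
#' Dispersal buffers are built once from the original current-range
#' geometry and held fixed across iterations (restored pixels do not act
#' as stepping stones). The area cap and habitat minima are computed
#' from the initial analyzable pixel set and held fixed; already-selected
#' pixels leave the candidate set permanently.
#'
#' @param bundle A [landscape_bundle()].
#' @param profiles List of [species_profile()] objects.
#' @param config A [scenario_config()].
#' @return An object of class `restoration_scenario` with the labelled
#'   selection surface (`0` = unselected, `k` = chosen in iteration k),
#'   per-iteration and per-species accounting tibbles, and the scenario
#'   report. See [tidy.restoration_scenario()] and
#'   [glance.restoration_scenario()].
#' @export
run_scenario <- function(bundle, profiles, config = scenario_config()) {
  stopifnot(inherits(bundle, "landscape_bundle"), inherits(config, "scenario_config"))
  profiles <- as_profile_list(profiles)
  prepared <- prepare_bundle(bundle, config)
  grid <- prepared$grid
  available <- compute_available_area(prepared$habitat, prepared$landcover,
                                      config$restorable_codes)

  # static per-species structures: eligibility, dispersal weights, suitability
  elig <- lapply(profiles, species_eligibility, available = available)
  disp <- lapply(profiles, dispersal_weight_surface, mode = config$dispersal_mode,
                 grid = grid)
  suit <- lapply(profiles, function(p) {
    if (!config$use_suitability) return(NULL)
    s <- prepared$suitability[[p$name]]
    if (is.null(s)) stop("no suitability surface supplied for species '", p$name, "'")
    s
  })
  names(elig) <- names(disp) <- names(suit) <- vapply(profiles, `[[`, character(1), "name")

  analyzable <- !is.na(available$values) & !is.na(prepared$cost$values)
  n_total <- sum(analyzable)
  if (n_total == 0) stop("no analyzable pixels: empty available area or cost layer")
  habitat_totals <- table(available$values[analyzable])
  habitat_totals <- stats::setNames(as.integer(habitat_totals), names(habitat_totals))

  states0 <- species_states(profiles)
  states <- states0
  weights <- vapply(profiles, `[[`, numeric(1), "weight")
  px_km2 <- pixel_area_km2(grid)

  labels <- matrix(0L, grid$n_rows, grid$n_cols)
  labels[!analyzable] <- NA_integer_
  iter_rows <- list()
  states_by_iter <- list(states0)

  for (it in seq_len(config$n_iterations)) {
    surfaces <- lapply(seq_along(profiles), function(k) {
      p <- profiles[[k]]
      species_benefit_surface(p, states[states$species == p$name, ],
                              available,
                              dispersal_weights = disp[[p$name]],
                              suitability = suit[[p$name]],
                              z = config$z, eligibility = elig[[p$name]])
    })
    total <- aggregate_benefit(surfaces, weights = weights, available = available)
    problem <- tryCatch(
      build_problem(total, prepared$cost, available, config,
                    candidate = analyzable & labels == 0L,
                    n_total = n_total, habitat_totals = habitat_totals),
      error = function(e) stop("iteration ", it, ": ", conditionMessage(e), call. = FALSE)
    )
    selection <- tryCatch(solve_site_selection(problem),
                          error = function(e) stop("iteration ", it, ": ",
                                                   conditionMessage(e), call. = FALSE))
    labels[selection$pixels$idx] <- it

    newly <- matrix(FALSE, grid$n_rows, grid$n_cols)
    newly[selection$pixels$idx] <- TRUE
    for (k in seq_along(profiles)) {
      p <- profiles[[k]]
      counts_mask <- elig[[p$name]]
      if (config$a_c_update == "within_buffer" && config$dispersal_mode != "none") {
        counts_mask <- counts_mask & disp[[p$name]]$values > 0
      }
      n_new <- sum(newly & counts_mask)
      states$area_current_km2[states$species == p$name] <-
        states$area_current_km2[states$species == p$name] + n_new * px_km2
    }
    states_by_iter[[it + 1]] <- states
    iter_rows[[it]] <- tibble::tibble(
      iteration = it,
      n_selected = selection$n_selected,
      cap_n = selection$cap_n,
      area_ha = selection$n_selected * selection$pixel_area_ha,
      cost_usd = selection$total_cost_usd,
      objective = selection$objective
    )
  }

  selection_surface <- categorical_surface(grid, labels)
  out <- structure(
    list(selection = selection_surface,
         iterations = dplyr::bind_rows(iter_rows),
         states_before = states0, states_after = states,
         states_by_iteration = states_by_iter,
         available = available, cost = prepared$cost,
         n_total = n_total, habitat_totals = habitat_totals,
         config = config, grid = grid,
         species = vapply(profiles, `[[`, character(1), "name")),
    class = "restoration_scenario"
  )
  out$report <- scenario_report(out)
  out
}

#' @export
print.restoration_scenario <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<restoration_scenario> '%s': %d pixels (%.4g km2) over %d iteration(s)\n",
              x$config$label, g$n_selected, g$area_km2, x$config$n_iterations))
  cat(sprintf("  total cost $%s, mean $%d/ha (nearest $10)\n",
              format(round(g$total_cost_usd), big.mark = ","), g$avg_cost_usd_ha_display))
  invisible(x)
}

#' Compare scenarios run on one landscape
#'
#' Binds the per-scenario summaries into one table and computes the
#' intersection mask: the pixels selected in *every* scenario, the
#' selections robust to the modeling assumptions being varied.
#'
#' @param ... Two or more `restoration_scenario` objects (or one list).
#' @return List with `table` (one [glance.restoration_scenario()] row
#'   per scenario) and `intersection` (binary surface of pixels chosen
#'   in all scenarios).
#' @export
compare_scenarios <- function(...) {
  scenarios <- list(...)
  if (length(scenarios) == 1 && !inherits(scenarios[[1]], "restoration_scenario")) {
    scenarios <- scenarios[[1]]
  }
  stopifnot(length(scenarios) >= 2,
            all(vapply(scenarios, inherits, logical(1), "restoration_scenario")))
  g <- scenarios[[1]]$grid
  for (s in scenarios[-1]) stop_if_grid_mismatch(g, s$grid, "scenario selections")
  inter <- Reduce(`&`, lapply(scenarios, function(s) {
    v <- s$selection$values
    !is.na(v) & v > 0L
  }))
  list(
    table = dplyr::bind_rows(lapply(scenarios, glance)),
    intersection = categorical_surface(g, matrix(as.integer(inter), g$n_rows, g$n_cols))
  )
}
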