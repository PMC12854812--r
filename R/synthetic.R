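#' Specification for a synthetic landscape bundle
#'
#' Defines the statistical shape of a generated study region. Defaults
#' emulate a Great-Plains-like setting at the analysis resolution used
#' throughout: a 200 x 200 grid of 960 m cells (about 192 x 192 km),
#' three historical prairie community classes laid out as noisy
#' west-to-east bands (shortgrass / mixed-grass / tallgrass gradient),
#' about 32% of the land in restorable cover (pasture/hay 81 and
#' cropland 82), a spatially autocorrelated lognormal land-value surface
#' with median $2,500/ha (stored in ln USD/ha, as land-value data are
#' distributed), five indicator species with nested blob ranges whose
#' current area is half their historical area, and smooth climate
#' suitability surfaces in `[0, 1]`.
#'
#' All randomness flows from the single integer `seed` through a fixed
#' splitting scheme (one derived sub-seed per layer and per species), so
#' an identical spec yields a bit-identical bundle.
#'
#' @param seed Integer master seed.
#' @param n_rows,n_cols,cell_size Grid shape (meters).
#' @param n_habitat_classes Number of habitat community classes (2-4).
#' @param habitat_patch_scale Characteristic patch scale in cells for
#'   the habitat tessellation and land-cover clumping.
#' @param layout `"banded"` (classes in longitudinal bands, the prairie
#'   gradient) or `"mosaic"` (fully random tessellation).
#' @param restorable_fraction Target fraction of cells with restorable
#'   land cover.
#' @param cost_log_mean,cost_log_sd Mean and SD of the ln USD/ha cost
#'   field.
#' @param cost_autocorr_scale Gaussian smoothing scale (cells) of the
#'   cost field.
#' @param species_specs Tibble with one row per species: `name`,
#'   `preferred_habitat_codes` (semicolon-joined), `dispersal_km`,
#'   `weight`, `n_blobs`, `blob_radius_km`. `NULL` uses a built-in
#'   five-species set spanning the habitat classes.
#' @param current_historical_ratio Current/historical range area ratio
#'   in (0, 1].
#' @param suitability_smoothness Smoothing scale (cells) of suitability
#'   fields.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_rows = 200L, n_cols = 200L, cell_size = 960,
                           n_habitat_classes = 3L,
                           habitat_patch_scale = 15,
                           layout = c("banded", "mosaic"),
                           restorable_fraction = 0.32,
                           cost_log_mean = log(2500), cost_log_sd = 0.5,
                           cost_autocorr_scale = 8,
                           species_specs = NULL,
                           current_historical_ratio = 0.5,
                           suitability_smoothness = 12) {
  layout <- match.arg(layout)
  stopifnot(n_habitat_classes >= 2, n_habitat_classes <= 4,
            habitat_patch_scale > 0, cost_autocorr_scale > 0,
            suitability_smoothness > 0, cost_log_sd > 0)
  if (restorable_fraction <= 0 || restorable_fraction > 1) {
    stop("restorable_fraction must lie in (0, 1]")
  }
  if (current_historical_ratio <= 0 || current_historical_ratio > 1) {
    stop("current_historical_ratio must lie in (0, 1]")
  }
  if (is.null(species_specs)) {
    species_specs <- default_species_specs(n_habitat_classes)
  }
  req <- c("name", "preferred_habitat_codes", "dispersal_km", "weight",
           "n_blobs", "blob_radius_km")
  stopifnot(all(req %in% names(species_specs)))
  structure(
    list(seed = as.integer(seed), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), cell_size = cell_size,
         n_habitat_classes = as.integer(n_habitat_classes),
         habitat_patch_scale = habitat_patch_scale, layout = layout,
         restorable_fraction = restorable_fraction,
         cost_log_mean = cost_log_mean, cost_log_sd = cost_log_sd,
         cost_autocorr_scale = cost_autocorr_scale,
         species_specs = tibble::as_tibble(species_specs),
         current_historical_ratio = current_historical_ratio,
         suitability_smoothness = suitability_smoothness),
    class = "synthetic_spec"
  )
}

# Five indicator species spanning the habitat gradient, loosely shaped
# on the grassland specialists of the Kansas prairies: a tallgrass
# grouse, a short/mixed-grass grouse, a mesocarnivore, a wide-ranging
# ungulate, and a low-vagility prairie butterfly. Dispersal distances
# are field-typical orders of magnitude (km per generation).
default_species_specs <- function(n_classes = 3L) {
  top <- n_classes            # highest code = easternmost band (tallgrass)
  mid <- max(2L, n_classes - 1L)
  tibble::tibble(
    name = c("tallgrass_grouse", "shortgrass_grouse", "prairie_fox",
             "prairie_ungulate", "prairie_butterfly"),
    preferred_habitat_codes = c(paste(top), "1;2", "1;2", "1;2",
                                paste(mid, top, sep = ";")),
    dispersal_km = c(15, 15, 30, 50, 5),
    weight = 1,
    n_blobs = c(2L, 2L, 2L, 2L, 3L),
    blob_radius_km = c(45, 50, 55, 60, 35)
  )
}

# Derived sub-seed: one integer stream per component, reproducible and
# independent of evaluation order.
sub_seed <- function(seed, k) (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian smoothing with reflection padding, used for every
# autocorrelated synthetic field.
gauss_smooth <- function(m, scale) {
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  smooth_vec <- function(x) {
    n <- length(x)
    pad <- c(x[pmin(half:1, n)], x, x[pmax(n - (1:half) + 1, 1)])
    stats::convolve(pad, rev(k), type = "filter")
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(m, 1, smooth_vec))
}

smoothed_noise <- function(n_rows, n_cols, scale) {
  gauss_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), scale)
}

circle_ring <- function(cx, cy, r, n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a complete synthetic landscape bundle
#'
#' Builds every input layer the pipeline consumes from a single seed:
#'
#' * habitat communities by nearest-seed-point tessellation (seed points
#'   stratified into longitudinal bands under the `"banded"` layout);
#' * land cover with exactly the target restorable fraction, spatially
#'   clumped, split between codes 81 and 82;
#' * a cost surface `exp(mean + sd * Z)` where `Z` is a standardized
#'   smoothed Gaussian field, stored in ln USD/ha so the pipeline's
#'   dollar conversion is exercised;
#' * per species, a historical range that is a union of disjoint
#'   circular blobs and a nested current range (the same blobs shrunk
#'   radially), so the current/historical area ratio is met exactly;
#' * per species, a smooth suitability surface rescaled to `[0, 1]`.
#'
#' Species whose eligible area (historical range x preferred habitat x
#' restorable cells) would be empty are re-drawn with a fresh sub-seed
#' up to 10 times, then an error is raised.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `bundle` (a [landscape_bundle()]) and
#'   `profiles` (list of [species_profile()]).
#' @examples
#' sim <- generate_bundle(synthetic_spec(seed = 42, n_rows = 60, n_cols = 60))
#' sim$bundle
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- rp_grid(spec$n_rows, spec$n_cols, cell_size = spec$cell_size,
                  crs_id = "synthetic-albers")
  habitat <- synth_habitat(spec, grid)
  landcover <- synth_landcover(spec, grid)
  cost <- synth_cost(spec, grid)
  available <- suppressWarnings(compute_available_area(habitat, landcover))

  profiles <- list()
  suitability <- list()
  for (i in seq_len(nrow(spec$species_specs))) {
    row <- spec$species_specs[i, ]
    profile <- NULL
    for (try in 0:9) {
      cand <- synth_species(spec, grid, row, seed_offset = 10 + i + 1000 * try)
      if (any(species_eligibility(cand, available))) { profile <- cand; break }
    }
    if (is.null(profile)) {
      stop("species '", row$name, "': no eligible restorable area after 10 range draws")
    }
    profiles[[i]] <- profile
    suitability[[row$name]] <- synth_suitability(spec, grid, seed_offset = 100 + i)
  }
  list(bundle = landscape_bundle(habitat, landcover, cost, suitability),
       profiles = as_profile_list(profiles))
}

synth_habitat <- function(spec, grid) {
  with_seed(sub_seed(spec$seed, 1), {
    n <- spec$n_habitat_classes
    seeds_per_class <- max(3L, round(grid$n_cols / spec$habitat_patch_scale))
    sx <- sy <- cls <- numeric(0)
    for (a in seq_len(n)) {
      if (spec$layout == "banded") {
        lo <- (a - 1) / n * grid$n_cols; hi <- a / n * grid$n_cols
      } else {
        lo <- 0; hi <- grid$n_cols
      }
      sx <- c(sx, stats::runif(seeds_per_class, lo, hi))
      sy <- c(sy, stats::runif(seeds_per_class, 0, grid$n_rows))
      cls <- c(cls, rep(a, seeds_per_class))
    }
    ci <- rep(seq_len(grid$n_cols), each = grid$n_rows) - 0.5
    ri <- rep(seq_len(grid$n_rows), times = grid$n_cols) - 0.5
    d2 <- outer(ci, sx, `-`)^2 + outer(ri, sy, `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    codes <- matrix(cls[nearest], grid$n_rows, grid$n_cols)
    categorical_surface(grid, codes)
  })
}

synth_landcover <- function(spec, grid) {
  with_seed(sub_seed(spec$seed, 2), {
    clump <- smoothed_noise(grid$n_rows, grid$n_cols, spec$habitat_patch_scale / 2)
    thr <- stats::quantile(clump, 1 - spec$restorable_fraction)
    restorable <- clump >= thr
    split_field <- smoothed_noise(grid$n_rows, grid$n_cols, spec$habitat_patch_scale)
    codes <- matrix(71L, grid$n_rows, grid$n_cols) # non-restorable grassland/shrub
    codes[restorable & split_field >= stats::median(split_field)] <- 81L
    codes[restorable & split_field < stats::median(split_field)] <- 82L
    categorical_surface(grid, codes)
  })
}

synth_cost <- function(spec, grid) {
  with_seed(sub_seed(spec$seed, 3), {
    f <- smoothed_noise(grid$n_rows, grid$n_cols, spec$cost_autocorr_scale)
    z <- (f - mean(f)) / stats::sd(f)
    continuous_surface(grid, spec$cost_log_mean + spec$cost_log_sd * z,
                       units = "ln USD/ha")
  })
}

synth_species <- function(spec, grid, row, seed_offset) {
  with_seed(sub_seed(spec$seed, seed_offset), {
    extent_x <- grid$n_cols * grid$cell_size
    extent_y <- grid$n_rows * grid$cell_size
    n_blobs <- row$n_blobs
    base_r <- row$blob_radius_km * 1000
    centers <- matrix(NA_real_, 0, 2)
    radii <- numeric(0)
    tries <- 0
    while (nrow(centers) < n_blobs && tries < 500) {
      tries <- tries + 1
      r <- base_r * stats::runif(1, 0.7, 1.3)
      cx <- grid$origin_x + stats::runif(1, 0.1, 0.9) * extent_x
      cy <- grid$origin_y + stats::runif(1, 0.1, 0.9) * extent_y
      # blobs must stay disjoint so planar areas add exactly
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < (radii + r) * 1.05)) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }
    if (nrow(centers) < n_blobs) {
      # crowded draw: fall back to however many disjoint blobs fit (>= 1)
      if (nrow(centers) == 0) stop("could not place any range blob")
    }
    shrink <- sqrt(spec$current_historical_ratio)
    hist_rings <- lapply(seq_along(radii), function(k) {
      circle_ring(centers[k, 1], centers[k, 2], radii[k])
    })
    curr_rings <- lapply(seq_along(radii), function(k) {
      circle_ring(centers[k, 1], centers[k, 2], radii[k] * shrink)
    })
    species_profile(
      name = row$name,
      preferred_habitat_codes = as.integer(strsplit(row$preferred_habitat_codes, ";")[[1]]),
      dispersal_km = row$dispersal_km,
      weight = row$weight,
      current_range = range_geometry(curr_rings, role = "current"),
      historical_range = range_geometry(hist_rings, role = "historical")
    )
  })
}

synth_suitability <- function(spec, grid, seed_offset) {
  with_seed(sub_seed(spec$seed, seed_offset), {
    f <- smoothed_noise(grid$n_rows, grid$n_cols, spec$suitability_smoothness)
    v <- (f - min(f)) / (max(f) - min(f))
    continuous_surface(grid, v, units = "suitability")
  })
}

#' A tiny fixed worked-example bundle
#'
#' A hand-coded 6 x 6 landscape on 100 m cells (1-ha pixels), used in
#' the documentation and in exact-value tests: three habitat bands
#' (codes 1/2/3, two columns each), a land-cover map with 29 restorable
#' cells (codes 81/82) and 7 excluded cells, an integer cost surface
#' in USD/ha, and two species - a grassland bird preferring habitats
#' {1, 2} whose ranges cover the western two-thirds, and a butterfly
#' preferring habitat {3} in the east - each with a current/historical
#' area ratio of exactly 0.5. Every layer is written out explicitly in
#' the source, so selections can be verified by hand or by exhaustive
#' enumeration.
#'
#' @return List with `bundle` and `profiles`, as [generate_bundle()].
#' @export
generate_worked_example <- function() {
  grid <- rp_grid(6, 6, cell_size = 100, crs_id = "synthetic-albers")
  habitat <- categorical_surface(grid, matrix(rep(c(1L, 1L, 2L, 2L, 3L, 3L), each = 6), 6, 6))
  landcover <- categorical_surface(grid, matrix(c(
    81, 81, 82, 82, 71, 81,
    81, 24, 82, 82, 81, 81,
    82, 81, 81, 71, 81, 82,
    82, 82, 71, 82, 82, 81,
    71, 81, 82, 82, 11, 82,
    81, 82, 81, 82, 82, 71), 6, 6, byrow = TRUE))
  cost <- continuous_surface(grid, matrix(c(
    2000, 2200, 1800, 2600, 3000, 3400,
    1900, 2500, 2100, 2400, 3200, 3100,
    2300, 1700, 2000, 2800, 2900, 3300,
    2100, 2600, 2200, 1900, 2700, 3500,
    2400, 2000, 2500, 2300, 3100, 2800,
    2200, 1800, 2600, 2100, 3000, 3600), 6, 6, byrow = TRUE),
    units = "USD/ha")
  rect <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  bird <- species_profile(
    name = "meadow_bird", preferred_habitat_codes = c(1L, 2L),
    dispersal_km = 0.2,
    current_range = range_geometry(rect(-300, 0, 50, 600), "current"),
    historical_range = range_geometry(rect(-300, 0, 400, 600), "historical")
  )
  butterfly <- species_profile(
    name = "prairie_butterfly", preferred_habitat_codes = 3L,
    dispersal_km = 0.1,
    current_range = range_geometry(rect(500, 0, 700, 600), "current"),
    historical_range = range_geometry(rect(300, 0, 700, 600), "historical")
  )
  list(bundle = landscape_bundle(habitat, landcover, cost),
       profiles = list(bird, butterfly))
}
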