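# Small construction helpers shared across test files. Everything is
# built in code; no fixture files.

# Wrap parallel vectors into a 1 x n landscape problem. 100 m cells make
# one pixel exactly 1 ha, so cost_per_ha is also cost per pixel.
problem_from_vectors <- function(benefit, cost_per_ha, habitat = rep(1L, length(benefit)),
                                 cap_pixels = length(benefit),
                                 min_frac_total = 0, n_iterations = 1,
                                 budget_usd = NULL) {
  n <- length(benefit)
  g <- rp_grid(1, n, cell_size = 100)
  avail <- compute_available_area(
    categorical_surface(g, matrix(as.integer(habitat), 1)),
    categorical_surface(g, matrix(81L, 1, n))
  )
  b <- continuous_surface(g, matrix(benefit, 1), "risk reduction")
  class(b) <- c("total_benefit", class(b))
  cost <- continuous_surface(g, matrix(cost_per_ha, 1), "USD/ha")
  frac <- min((cap_pixels + 0.5) / n, 1) # floor() recovers cap_pixels exactly
  cfg <- scenario_config(per_iteration_fraction = frac,
                         target_fraction = frac * n_iterations,
                         n_iterations = n_iterations,
                         min_habitat_fraction_total = min_frac_total,
                         budget_usd = budget_usd)
  build_problem(b, cost, avail, cfg)
}

# Seeded random instance for solver exactness checks.
random_problem <- function(seed, n, n_classes = 3, min_frac_total = 0,
                           cap_frac = 0.5, zero_benefit_rate = 0.15) {
  set.seed(seed)
  benefit <- stats::runif(n)
  benefit[stats::runif(n) < zero_benefit_rate] <- 0
  cost <- round(stats::runif(n, 500, 5000))
  habitat <- c(seq_len(n_classes), sample.int(n_classes, n - n_classes, replace = TRUE))
  problem_from_vectors(benefit, cost, habitat,
                       cap_pixels = floor(cap_frac * n),
                       min_frac_total = min_frac_total)
}

# A compact seeded synthetic bundle for property tests.
small_bundle <- function(seed = 1, n = 60) {
  generate_bundle(synthetic_spec(seed = seed, n_rows = n, n_cols = n,
                                 habitat_patch_scale = 8,
                                 cost_autocorr_scale = 4,
                                 suitability_smoothness = 5))
}
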