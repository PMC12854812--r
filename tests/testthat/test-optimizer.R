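test_that("top-k-by-ratio selection on an unconstrained instance", {
  # equal costs, descending benefits -> ratios (5,4,3,2,1,0), cap 3
  p <- problem_from_vectors(benefit = c(5, 4, 3, 2, 1, 0) * 1e-4,
                            cost_per_ha = rep(1000, 6), cap_pixels = 3)
  sel <- solve_site_selection(p)
  expect_equal(sort(sel$pixels$col), 1:3)
  expect_equal(sel$objective, sum(p$pixels$ratio[1:3]))
})

test_that("habitat minima are honored and infeasible instances error out", {
  # cap 3, three classes, one pixel minimum each (frac 1/3 over 1 iteration)
  p <- problem_from_vectors(benefit = c(9, 8, 7, 1, 0.5, 0.1) * 1e-4,
                            cost_per_ha = rep(1000, 6),
                            habitat = c(1L, 1L, 1L, 2L, 2L, 3L),
                            cap_pixels = 3, min_frac_total = 0.2)
  sel <- solve_site_selection(p)
  expect_setequal(sel$pixels$habitat, 1:3)
  expect_equal(sel$objective, brute_force_objective(p), tolerance = 1e-12)

  # summed minima exceeding the cap is contradictory
  expect_error(problem_from_vectors(benefit = rep(1e-4, 6), cost_per_ha = rep(1000, 6),
                                    habitat = rep(1:3, each = 2),
                                    cap_pixels = 2, min_frac_total = 0.9),
               "infeasible")
  # a habitat with too few candidates is named
  g <- rp_grid(1, 4, cell_size = 100)
  avail <- compute_available_area(categorical_surface(g, matrix(c(1L, 1L, 1L, 2L), 1)),
                                  categorical_surface(g, matrix(81L, 1, 4)))
  b <- continuous_surface(g, matrix(1e-4, 1, 4), "risk reduction")
  cost <- continuous_surface(g, matrix(1000, 1, 4), "USD/ha")
  cfg <- scenario_config(per_iteration_fraction = 0.9, target_fraction = 0.9,
                         n_iterations = 1, min_habitat_fraction_total = 0.6)
  expect_error(build_problem(b, cost, avail, cfg,
                             candidate = matrix(c(TRUE, TRUE, TRUE, FALSE), 1),
                             n_total = 4,
                             habitat_totals = c("1" = 3L, "2" = 1L)),
               "habitat 2")
})

test_that("zero-benefit problems return the cheapest feasible selection", {
  p <- problem_from_vectors(benefit = rep(0, 6),
                            cost_per_ha = c(3000, 1000, 2000, 2500, 1500, 1200),
                            habitat = c(1L, 1L, 1L, 2L, 2L, 2L),
                            cap_pixels = 4, min_frac_total = 0.17)
  sel <- solve_site_selection(p)
  # one pixel per habitat minimum, chosen by lowest cost; no filler beyond minima
  expect_equal(sort(sel$pixels$cost_usd), c(1000, 1200))
  expect_equal(sel$objective, 0)
})

test_that("exact solver matches exhaustive enumeration on constrained instances", {
  agree <- 0
  for (seed in 1:40) {
    n <- sample(8:14, 1)
    p <- tryCatch(random_problem(seed * 13, n, n_classes = 3,
                                 min_frac_total = sample(c(0, 0.2, 0.34), 1)),
                  error = function(e) NULL)
    if (is.null(p)) { agree <- agree + 1; next } # infeasible by construction
    expect_equal(solve_site_selection(p)$objective, brute_force_objective(p),
                 tolerance = 1e-12)
    agree <- agree + 1
  }
  expect_equal(agree, 40)
})

test_that("greedy reference equals the exact solver without minima, and rejects minima", {
  for (seed in c(2, 9, 31)) {
    p <- random_problem(seed, n = 500, min_frac_total = 0)
    expect_identical(greedy_reference(p)$pixels$idx, solve_site_selection(p)$pixels$idx)
  }
  p_min <- random_problem(4, 30, min_frac_total = 0.34)
  expect_error(greedy_reference(p_min), "habitat minima")
  # empty positive-ratio pool -> empty greedy selection
  p0 <- problem_from_vectors(benefit = rep(0, 4), cost_per_ha = rep(1000, 4), cap_pixels = 2)
  expect_equal(greedy_reference(p0)$n_selected, 0)
})

test_that("relaxing habitat minima never decreases the optimum", {
  for (seed in 1:10) {
    with_min <- random_problem(seed, 12, min_frac_total = 0.25)
    no_min <- random_problem(seed, 12, min_frac_total = 0)
    expect_gte(solve_site_selection(no_min)$objective + 1e-12,
               solve_site_selection(with_min)$objective)
  }
})

test_that("budget mode maximizes benefit under a cost cap, exactly", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 10
    benefit <- runif(n); cost <- round(runif(n, 500, 5000))
    p <- problem_from_vectors(benefit, cost, habitat = rep(1:2, length.out = n),
                              cap_pixels = n, budget_usd = 8000)
    sel <- solve_site_selection(p)
    expect_equal(sel$objective, brute_force_objective(p), tolerance = 1e-10)
    expect_lte(sel$total_cost_usd, 8000 + 1e-6)
  }
})
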