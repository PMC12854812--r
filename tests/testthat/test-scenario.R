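test_that("config invariants are enforced", {
  expect_error(scenario_config(n_iterations = 3, per_iteration_fraction = 0.2,
                               target_fraction = 0.3),
               "must equal target_fraction")
  expect_error(scenario_config(target_fraction = 1.2, per_iteration_fraction = 0.4),
               "\\[0, 1\\]")
  expect_error(scenario_config(z = 1.2), "z")
  cfg <- scenario_config()
  expect_equal(cfg$n_iterations * cfg$per_iteration_fraction, cfg$target_fraction,
               tolerance = 1e-12)
})

test_that("yaml configs round-trip with overrides and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dispersal_mode: natural", "z: 0.3", "min_habitat_fraction_total: 0.1"), f)
  cfg <- read_scenario_config(f)
  expect_equal(cfg$dispersal_mode, "natural")
  expect_equal(cfg$z, 0.3)
  cfg2 <- read_scenario_config(f, z = 0.1)
  expect_equal(cfg2$z, 0.1)
  writeLines("not_a_key: 1", f)
  expect_error(read_scenario_config(f), "unknown configuration key")
})

test_that("the worked example selects the enumeration-optimal pixel set", {
  we <- generate_worked_example()
  cfg1 <- scenario_config(n_iterations = 1, target_fraction = 6.5 / 29,
                          per_iteration_fraction = 6.5 / 29,
                          min_habitat_fraction_total = 0)
  sc <- run_scenario(we$bundle, we$profiles, cfg1)
  got <- as.integer(sort(tidy(sc)$row + (tidy(sc)$col - 1) * 6))

  # independent oracle: exhaustive enumeration over all candidate subsets
  avail <- compute_available_area(we$bundle$habitat, we$bundle$landcover)
  st <- species_states(we$profiles)
  surfaces <- lapply(we$profiles, function(p)
    species_benefit_surface(p, st[st$species == p$name, ], avail))
  tot <- aggregate_benefit(surfaces, available = avail)
  # enumerate only over the 11 best-ratio candidates to keep 2^n tractable;
  # pixels outside can never enter an optimal 6-subset of a ratio sum
  prob <- build_problem(tot, we$bundle$cost, avail, cfg1)
  keep <- order(-prob$pixels$ratio)[1:11]
  prob_small <- prob
  prob_small$pixels <- prob$pixels[keep, ]
  want <- brute_force_selection(prob_small)
  expect_identical(got, want)

  # frozen documented set: the five best butterfly pixels in the eastern
  # tallgrass band plus the single cheapest bird pixel (row 3, col 2)
  expect_identical(got, c(9L, 27L, 28L, 30L, 32L, 35L))
  expect_equal(sum(we$bundle$cost$values[got]), 16200)
})

test_that("the worked example with binding habitat minima matches enumeration", {
  we <- generate_worked_example()
  cfg <- scenario_config(n_iterations = 1, target_fraction = 6.5 / 29,
                         per_iteration_fraction = 6.5 / 29,
                         min_habitat_fraction_total = 0.15)
  sc <- run_scenario(we$bundle, we$profiles, cfg)
  avail <- sc$available
  # minima: ceil(0.15 * {10, 10, 9}) = 2 per habitat class
  hs <- habitat_area_summary(sc)
  expect_true(all(hs$n_pixels >= 2))
  expect_equal(sum(hs$n_pixels), 6)

  st <- species_states(we$profiles)
  surfaces <- lapply(we$profiles, function(p)
    species_benefit_surface(p, st[st$species == p$name, ], avail))
  tot <- aggregate_benefit(surfaces, available = avail)
  prob <- build_problem(tot, we$bundle$cost, avail, cfg)
  # minima sum to the cap, so an optimum takes the top pixels per class;
  # enumerating each class's five best ratios is exhaustive with margin
  keep <- unlist(lapply(split(seq_len(nrow(prob$pixels)), prob$pixels$habitat),
                        function(i) i[order(-prob$pixels$ratio[i],
                                            prob$pixels$cost_usd[i])][1:5]))
  prob_small <- prob
  prob_small$pixels <- prob$pixels[keep, ]
  want <- brute_force_selection(prob_small)
  got <- as.integer(sort(tidy(sc)$row + (tidy(sc)$col - 1) * 6))
  expect_identical(got, want)
})

test_that("a single-iteration run at the full target equals the degenerate loop", {
  we <- generate_worked_example()
  one <- run_scenario(we$bundle, we$profiles,
                      scenario_config(n_iterations = 1, target_fraction = 0.3,
                                      per_iteration_fraction = 0.3,
                                      min_habitat_fraction_total = 0))
  expect_equal(nrow(one$iterations), 1)
  expect_lte(one$report$costs$n_selected, floor(0.3 * one$n_total))
})

test_that("iterating updates species areas monotonically and shrinks benefits", {
  sim <- small_bundle(seed = 5)
  sc <- run_scenario(sim$bundle, sim$profiles,
                     scenario_config("none", min_habitat_fraction_total = 0.2))
  states <- sc$states_by_iteration
  for (k in seq_len(length(states) - 1)) {
    expect_true(all(states[[k + 1]]$area_current_km2 >= states[[k]]$area_current_km2))
  }
  expect_true(all(sc$states_after$area_current_km2 >= sc$states_before$area_current_km2))
  # per-iteration objectives decrease: diminishing returns flow into selection
  expect_true(all(diff(sc$iterations$objective) < 0))
  # caps hold exactly each iteration
  expect_true(all(sc$iterations$n_selected <= sc$iterations$cap_n))
  # iteration labels partition the selection
  expect_setequal(unique(tidy(sc)$iteration), 1:3)
})

test_that("scenario runs are deterministic and comparable", {
  sim <- small_bundle(seed = 2)
  cfg <- scenario_config("intermediate", min_habitat_fraction_total = 0.1, label = "a")
  s1 <- run_scenario(sim$bundle, sim$profiles, cfg)
  s2 <- run_scenario(sim$bundle, sim$profiles, cfg)
  expect_identical(s1$selection$values, s2$selection$values)

  s3 <- run_scenario(sim$bundle, sim$profiles,
                     scenario_config("natural", min_habitat_fraction_total = 0.1, label = "b"))
  cmp <- compare_scenarios(s1, s3)
  expect_equal(nrow(cmp$table), 2)
  # identical configs -> intersection equals the selection
  cmp_same <- compare_scenarios(s1, s2)
  expect_identical(cmp_same$intersection$values,
                   matrix(as.integer(!is.na(s1$selection$values) & s1$selection$values > 0),
                          nrow = 60))
  # intersection mask is a subset of every selection
  expect_true(all(cmp$intersection$values <= (!is.na(s1$selection$values) & s1$selection$values > 0)))
  expect_true(all(cmp$intersection$values <= (!is.na(s3$selection$values) & s3$selection$values > 0)))
})

test_that("coarsened runs respect the transform-order switch", {
  sim <- small_bundle(seed = 8)
  cfg_a <- scenario_config("none", resolution_factor = 2, min_habitat_fraction_total = 0)
  cfg_b <- scenario_config("none", resolution_factor = 2, min_habitat_fraction_total = 0,
                           cost_transform_order = "coarsen_then_exp")
  sa <- run_scenario(sim$bundle, sim$profiles, cfg_a)
  sb <- run_scenario(sim$bundle, sim$profiles, cfg_b)
  expect_equal(sa$grid$cell_size, 1920)
  # arithmetic mean of dollars >= exp of mean logs (Jensen), cell-wise
  expect_true(all(sa$cost$values >= sb$cost$values - 1e-9, na.rm = TRUE))
})
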