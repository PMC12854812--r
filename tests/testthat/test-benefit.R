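# A deterministic 4x4 micro-landscape: habitat in two column bands plus a
# nodata hole, cropland on chosen cells only.
micro_landscape <- function() {
  g <- rp_grid(4, 4, cell_size = 100)
  hab <- matrix(c(1L, 1L, 2L, 2L,
                  1L, 1L, 2L, 2L,
                  1L, NA, 2L, 3L,
                  1L, 1L, 3L, 3L), 4, 4, byrow = TRUE)
  lc <- matrix(c(81L, 24L, 82L, 82L,
                 11L, 81L, 71L, 82L,
                 81L, 81L, 71L, 82L,
                 71L, 71L, 71L, 71L), 4, 4, byrow = TRUE)
  list(grid = g,
       habitat = categorical_surface(g, hab),
       landcover = categorical_surface(g, lc))
}

test_that("available area is the habitat-by-restorable intersection", {
  ml <- micro_landscape()
  av <- compute_available_area(ml$habitat, ml$landcover)
  # hand enumeration: cells with landcover 81/82 AND a habitat code
  want <- matrix(NA_integer_, 4, 4)
  want[1, 1] <- 1L; want[1, 3] <- 2L; want[1, 4] <- 2L
  want[2, 2] <- 1L; want[2, 4] <- 2L
  want[3, 1] <- 1L; want[3, 4] <- 3L
  expect_identical(av$values, want)

  all81 <- categorical_surface(ml$grid, matrix(81L, 4, 4))
  expect_identical(compute_available_area(ml$habitat, all81)$values, ml$habitat$values)

  none <- categorical_surface(ml$grid, matrix(11L, 4, 4))
  expect_warning(empty <- compute_available_area(ml$habitat, none), "empty")
  expect_true(all(is.na(empty$values)))

  g2 <- rp_grid(4, 4, cell_size = 200)
  expect_error(compute_available_area(ml$habitat, categorical_surface(g2, matrix(81L, 4, 4))),
               "alignment")
})

test_that("dispersal modes weight cells inside/outside the buffer as 1 / {1, 0.5, 0}", {
  g <- rp_grid(10, 10, cell_size = 100)
  sp <- species_profile("sp", 1L, dispersal_km = 0.2,
                        current_range = range_geometry(cbind(c(0, 300, 300, 0), c(700, 700, 1000, 1000)), "current"),
                        historical_range = range_geometry(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)), "historical"))
  w_none <- dispersal_weight_surface(sp, "none", g)
  expect_true(all(w_none$values == 1))
  w_int <- dispersal_weight_surface(sp, "intermediate", g)
  w_nat <- dispersal_weight_surface(sp, "natural", g)
  buf <- dispersal_buffer_mask(sp$current_range, 0.2, g)$values
  expect_true(all(w_int$values[buf == 1L] == 1) && all(w_int$values[buf == 0L] == 0.5))
  expect_true(all(w_nat$values[buf == 1L] == 1) && all(w_nat$values[buf == 0L] == 0))
})

test_that("species benefit is the weighted risk reduction on the eligible triple intersection", {
  ml <- micro_landscape()
  av <- compute_available_area(ml$habitat, ml$landcover)
  # historical range covers the west half (cols 1-2 centers); prefers habitat 1
  sp <- species_profile("w", 1L, dispersal_km = 0.1,
                        current_range = range_geometry(cbind(c(0, 100, 100, 0), c(0, 0, 400, 400)), "current"),
                        historical_range = range_geometry(cbind(c(0, 200, 200, 0), c(0, 0, 400, 400)), "historical"))
  st <- list(area_current_km2 = 0.04, area_original_km2 = 0.08)
  b <- species_benefit_surface(sp, st, av, z = 0.25)
  rr <- risk_reduction(0.04, 0.08, pixel_area_km2(ml$grid), 0.25)
  # eligible: available habitat-1 cells among cols 1-2 = (1,1), (2,2), (3,1)
  want <- matrix(0, 4, 4)
  want[1, 1] <- want[2, 2] <- want[3, 1] <- rr
  expect_equal(b$values, want)

  # suitability multiplies; zero suitability annihilates
  suit <- continuous_surface(ml$grid, matrix(0.5, 4, 4), "suitability")
  suit$values[1, 1] <- 0
  b2 <- species_benefit_surface(sp, st, av, suitability = suit, z = 0.25)
  expect_equal(b2$values[1, 1], 0)
  expect_equal(b2$values[2, 2], 0.5 * rr)

  bad <- continuous_surface(ml$grid, matrix(1.2, 4, 4), "suitability")
  expect_error(species_benefit_surface(sp, st, av, suitability = bad), "outside")
  # tiny numeric excursions clamp instead
  eps <- continuous_surface(ml$grid, matrix(1 + 1e-9, 4, 4), "suitability")
  b3 <- species_benefit_surface(sp, st, av, suitability = eps, z = 0.25)
  expect_equal(b3$values[2, 2], rr)
})

test_that("aggregation is a commutative weighted sum with union support", {
  ml <- micro_landscape()
  av <- compute_available_area(ml$habitat, ml$landcover)
  mk <- function(cells, value) {
    v <- matrix(0, 4, 4); v[cells] <- value
    s <- continuous_surface(ml$grid, v, "risk reduction")
    class(s) <- c("species_benefit", class(s)); s
  }
  s1 <- mk(cbind(1, 1), 0.001)
  s2 <- mk(cbind(2, 2), 0.001)
  s3 <- mk(rbind(c(1, 1), c(2, 2)), 0.001)
  tot <- aggregate_benefit(list(s1, s2, s3), weights = c(1, 1, 2))
  expect_equal(tot$values[1, 1], 0.003)
  expect_equal(tot$values[2, 2], 0.003)
  # commutativity
  tot_rev <- aggregate_benefit(list(s3, s2, s1), weights = c(2, 1, 1))
  expect_equal(tot$values, tot_rev$values)
  # single species, unit weight = identity
  expect_equal(aggregate_benefit(list(s1))$values, s1$values)
  # disjoint supports do not bleed into each other
  expect_equal(sum(aggregate_benefit(list(s1, s2))$values > 0), 2)
  # nodata restricted to the analyzable set when available is supplied
  tot_na <- aggregate_benefit(list(s1), available = av)
  expect_true(is.na(tot_na$values[4, 1]))
  expect_error(aggregate_benefit(list()), "at least one")
})

test_that("dispersal support ordering holds and benefits shrink as habitat accrues", {
  sim <- small_bundle(seed = 3)
  av <- compute_available_area(sim$bundle$habitat, sim$bundle$landcover)
  st <- species_states(sim$profiles)
  for (p in sim$profiles[1:2]) {
    s <- st[st$species == p$name, ]
    b <- lapply(c("none", "intermediate", "natural"), function(m) {
      w <- dispersal_weight_surface(p, m, sim$bundle$grid)
      species_benefit_surface(p, s, av, dispersal_weights = w)$values
    })
    names(b) <- c("none", "intermediate", "natural")
    supp <- lapply(b, function(v) v > 0)
    expect_true(all(supp$natural <= supp$intermediate))          # natural within intermediate
    expect_identical(supp$intermediate, supp$none)               # same support, halved weight
    expect_true(all(b$natural <= b$intermediate + 1e-15))
    expect_true(all(b$intermediate <= b$none + 1e-15))

    # diminishing returns: adding area strictly shrinks every positive cell
    s2 <- s; s2$area_current_km2 <- s$area_current_km2 + 50
    b_after <- species_benefit_surface(p, s2, av)$values
    b_before <- species_benefit_surface(p, s, av)$values
    expect_true(all(b_after[b_before > 0] < b_before[b_before > 0]))
  }
})
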