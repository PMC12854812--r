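test_that("pixel area follows the cell size", {
  expect_equal(pixel_area_ha(rp_grid(5, 5, cell_size = 960)), 92.16)
  expect_equal(pixel_area_ha(rp_grid(5, 5, cell_size = 480)), 23.04)
  expect_equal(pixel_area_ha(rp_grid(5, 5, cell_size = 100)), 1)
  expect_equal(pixel_area_km2(rp_grid(5, 5, cell_size = 960)), 0.9216)
})

test_that("grid construction rejects degenerate and geographic inputs", {
  expect_error(rp_grid(0, 3, cell_size = 100), "at least one")
  expect_error(rp_grid(3, 3, cell_size = -1), "cell_size")
  expect_error(rp_grid(3, 3, cell_size = 100, crs_id = "EPSG:4326"), "equal-area")
})

test_that("ascii-grid round trip is lossless for both surface kinds", {
  g <- rp_grid(3, 3, cell_size = 250, origin_x = 1000, origin_y = -500)
  cat_s <- categorical_surface(g, matrix(c(1L, 2L, NA, 1L, 1L, 2L, 2L, NA, 1L), 3, 3))
  f <- withr::local_tempfile(fileext = ".asc")
  write_surface(cat_s, f)
  back <- read_categorical(f)
  expect_identical(back$values, cat_s$values)
  expect_identical(unclass(back$grid), unclass(cat_s$grid))

  vals <- matrix(c(0.1234567890123, -2.5, NA, 1e6, pi, exp(1), 0, -1, 42), 3, 3)
  con_s <- continuous_surface(g, vals, units = "USD/ha")
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_surface(con_s, f2)
  back2 <- read_continuous(f2, units = "USD/ha")
  expect_equal(back2$values, con_s$values, tolerance = 1e-15)
  expect_identical(back2$units, "USD/ha")
})

test_that("categorical readers reject fractional values; degenerate files warn or fail", {
  g <- rp_grid(2, 2, cell_size = 100)
  f <- withr::local_tempfile(fileext = ".asc")
  write_surface(continuous_surface(g, matrix(c(1, 2, 2.5, 3), 2, 2)), f)
  expect_error(read_categorical(f), "non-integer")
  expect_error(read_categorical(withr::local_tempfile()), "no such file")

  f3 <- withr::local_tempfile(fileext = ".asc")
  write_surface(continuous_surface(g, matrix(NA_real_, 2, 2)), f3)
  expect_warning(read_continuous(f3), "all nodata")
})

test_that("log-scale costs exponentiate cell-wise with nodata propagated", {
  g <- rp_grid(1, 3, cell_size = 100)
  s <- continuous_surface(g, matrix(c(0, log(2500), NA), 1), units = "ln USD/ha")
  out <- exp_transform_cost(s)
  expect_equal(out$values[1, 1:2], c(1, 2500))
  expect_true(is.na(out$values[1, 3]))
  expect_identical(out$units, "USD/ha")
  expect_error(exp_transform_cost(out), "ln USD/ha")
})

test_that("coarsening averages continuous blocks and takes modal codes with low-code ties", {
  g <- rp_grid(2, 2, cell_size = 480)
  s <- continuous_surface(g, matrix(c(100, 300, 200, 400), 2, 2), "USD/ha")
  c2 <- coarsen(s, 2)
  expect_equal(c2$values[1, 1], 250)
  expect_equal(c2$grid$cell_size, 960)

  codes <- categorical_surface(g, matrix(c(1L, 2L, 1L, NA), 2, 2))
  expect_equal(coarsen(codes, 2)$values[1, 1], 1L)      # modal
  tie <- categorical_surface(g, matrix(c(2L, 1L, 1L, 2L), 2, 2))
  expect_equal(coarsen(tie, 2)$values[1, 1], 1L)        # tie -> lowest code
  all_na <- categorical_surface(g, matrix(NA_integer_, 2, 2))
  expect_true(is.na(coarsen(all_na, 2)$values[1, 1]))
  expect_error(coarsen(s, 1), "factor")
})

test_that("coarsening preserves the global mean on covered extents and pads partial blocks", {
  set.seed(11)
  g <- rp_grid(8, 8, cell_size = 100)
  s <- continuous_surface(g, matrix(runif(64), 8, 8), "x")
  expect_equal(mean(coarsen(s, 2)$values), mean(s$values), tolerance = 1e-12)
  expect_equal(mean(coarsen(s, 4)$values), mean(s$values), tolerance = 1e-12)

  g2 <- rp_grid(5, 5, cell_size = 100)
  s2 <- continuous_surface(g2, matrix(1:25, 5, 5) * 1.0, "x")
  c2 <- coarsen(s2, 2)
  expect_equal(dim(c2$values), c(3, 3))
  # trailing partial block = mean over its available cells only
  expect_equal(c2$values[3, 3], 25)
  # north edge stays anchored: top of extent unchanged
  expect_equal(c2$grid$origin_y + 3 * 200, g2$origin_y + 5 * 100)
})

test_that("surface tibble view exposes cell centers", {
  g <- rp_grid(2, 2, cell_size = 100, origin_x = 0, origin_y = 0)
  s <- continuous_surface(g, matrix(c(1, 2, 3, NA), 2, 2))
  d <- surface_tbl(s)
  expect_equal(nrow(d), 3)
  expect_equal(d$y[d$row == 1][1], 150) # row 1 is the northern row
  expect_equal(d$x[d$col == 2][1], 150)
})
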