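test_that("protons per spot follow from charge over elementary charge", {
  p <- spot_plan(0, 0, dwell_time_s = 10, current_nA = 6.0)
  expect_equal(p$protons, 6.0e-9 * 10 / 1.602176634e-19, tolerance = 1e-12)
  expect_error(spot_plan(0, 0, dwell_time_s = 0, current_nA = 6), "dwell")
  expect_error(spot_plan(0, 0, dwell_time_s = 1, current_nA = -1), "current")
})

test_that("a single centred spot has the closed-form central fluence", {
  p <- spot_plan(0, 0, 10, 6.0)
  sx <- 0.78; sy <- 0.89
  expect_equal(fluence_at(p, 0, 0, sx, sy),
               p$protons / (2 * pi * sx * sy) * 100, tolerance = 1e-12)
})

test_that("the nine-spot grid plan delivers the reference central fluence", {
  plan <- grid_plan_3x3()
  expect_equal(fluence_at(plan, 0, 0, 0.78, 0.89), 2.5e13,
               tolerance = 0.05)
})

test_that("fluence maps conserve the delivered protons to 0.1%", {
  plan <- grid_plan_3x3()
  fm <- fluence_map(plan, 0.78, 0.89)
  expect_equal(map_integral(fm), sum(plan$protons), tolerance = 1e-3)
  expect_true(all(fm$values >= 0))
})

test_that("insufficient grids are rejected", {
  plan <- grid_plan_3x3()
  expect_error(fluence_map(plan, 0.78, 0.89, extent = 2), "grid extent")
  expect_error(fluence_map(plan, 1.2, 1.2, extent = 6.2,
                           edge_action = "error"), NA)
})

test_that("surface dose is zero at zero fluence and linear in fluence", {
  tab <- water_table()
  expect_identical(surface_dose(0, 7.5, 100, tab), 0)
  d1 <- surface_dose(1e13, 7.5, 100, tab)
  expect_equal(surface_dose(2e13, 7.5, 100, tab), 2 * d1, tolerance = 1e-12)
})

test_that("the planned fluence deposits the reference surface dose in 100 um of water", {
  plan <- grid_plan_3x3()
  phi <- fluence_at(plan, 0, 0, 0.78, 0.89)
  expect_equal(surface_dose(phi, 7.5, 100, water_table()), 2.4e5,
               tolerance = 0.05)
})

test_that("a slab thicker than the residual range is rejected", {
  expect_error(surface_dose(1e13, 2.6, 200, water_table()),
               "exceeds the residual")
})

test_that("the dose map composes fluence and surface dose and peaks at the plan centre", {
  plan <- grid_plan_3x3()
  dm <- dose_map(plan, 0.78, 0.89, table = water_table())
  phi0 <- fluence_at(plan, 0, 0, 0.78, 0.89)
  d0 <- surface_dose(phi0, 7.5, 100, water_table())
  ic <- which.min(abs(dm$x)); jc <- which.min(abs(dm$y))
  expect_equal(dm$values[ic, jc], d0, tolerance = 1e-9)
  # dose is proportional to fluence everywhere
  ratio <- dm$values / dm$fluence$values
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
  # brute-force argmax lands on the grid centre for the symmetric plan
  amax <- arrayInd(which.max(dm$values), dim(dm$values))
  expect_equal(c(dm$x[amax[1]], dm$y[amax[2]]), c(0, 0))
})

test_that("dose homogeneity metrics behave sensibly", {
  plan <- grid_plan_3x3()
  dm <- dose_map(plan, 0.78, 0.89, table = water_table())
  h_small <- dose_homogeneity(dm, radius_mm = 0.5)
  h_large <- dose_homogeneity(dm, radius_mm = 3)
  expect_lt(h_small, h_large)  # variation grows with radius
  expect_gte(dose_homogeneity(dm, 2, "range_ratio"), 0)
  expect_lt(dose_homogeneity(dm, 2, "cv"),
            dose_homogeneity(dm, 2, "max_dev"))
  # a radius containing only the central cell is perfectly homogeneous
  expect_equal(dose_homogeneity(dm, 0.01), 0)
})

test_that("maps round-trip through the delimited-text exporter", {
  plan <- grid_plan_3x3()
  fm <- fluence_map(plan, 0.78, 0.89, pitch = 0.2)
  f <- tempfile(fileext = ".tsv")
  write_map(fm, f)
  back <- read_map(f)
  expect_equal(back$values, unname(fm$values), tolerance = 1e-12)
  expect_equal(back$pitch, fm$pitch)
  expect_equal(back$x, fm$x, tolerance = 1e-9)
  expect_gt(length(map_contours(fm)), 0)
})
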