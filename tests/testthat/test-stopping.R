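test_that("stopping-power interpolation is exact at nodes and monotone between them", {
  tab <- water_table()
  i <- c(5L, 20L, 40L)
  expect_equal(interpolate_sp(tab, tab$energies[i]), tab$mass_sp[i])
  # midway between two nodes the value lies in the bracketing interval
  Em <- sqrt(tab$energies[10] * tab$energies[11])
  v <- interpolate_sp(tab, Em)
  expect_true(v < tab$mass_sp[10] && v > tab$mass_sp[11])
})

test_that("interpolation at 7.5 MeV matches independent log-log arithmetic on the bracketing rows", {
  tab <- water_table()
  k <- max(which(tab$energies <= 7.5))
  E1 <- tab$energies[k]; E2 <- tab$energies[k + 1]
  S1 <- tab$mass_sp[k]; S2 <- tab$mass_sp[k + 1]
  frac <- (log(7.5) - log(E1)) / (log(E2) - log(E1))
  expected <- exp(log(S1) + frac * (log(S2) - log(S1)))
  expect_equal(interpolate_sp(tab, 7.5), expected, tolerance = 1e-12)
})

test_that("out-of-grid queries and invalid tables are rejected", {
  tab <- water_table()
  expect_error(interpolate_sp(tab, 0.01), "outside table grid")
  expect_error(interpolate_sp(tab, 100), "outside table grid")
  expect_error(stopping_power_table("x", 1, c(1, 1, 2), c(1, 2, 3)),
               "strictly increasing")
  expect_error(stopping_power_table("x", 1, c(1, 2), c(1, -2)), "positive")
  expect_error(stopping_power_table("x", -1, c(1, 2), c(1, 2)), "positive")
})

test_that("CSDA ranges reproduce the reference values for 7.5 and 2.6 MeV protons in water", {
  tab <- water_table()
  expect_equal(csda_range(tab, 7.5) * 10, 0.74, tolerance = 0.03)   # mm
  expect_equal(csda_range(tab, 2.6) * 1e4, 115, tolerance = 0.03)   # um
})

test_that("CSDA range is strictly increasing and continuous in energy", {
  tab <- water_table()
  E <- seq(1, 11, by = 0.5)
  R <- csda_range(tab, E)
  expect_true(all(diff(R) > 0))
  expect_gt(csda_range(tab, 8), csda_range(tab, 7.5))
  # continuity: a 0.1% energy step moves the range by < 0.5%
  expect_lt(abs(csda_range(tab, 5.005) / csda_range(tab, 5) - 1), 0.005)
})

test_that("energy degradation through the exit window and air gap loses 0.50 MeV", {
  bl <- beamline(list(list(material = "kapton", thickness_cm = 8e-4),
                      list(material = "air", thickness_cm = 7.5)),
                 entry_energy = 8.0)
  r <- energy_after_layers(bl)
  expect_equal(r$energy_lost, 0.50, tolerance = 0.05 / 0.50)
  expect_equal(r$exit_energy, 7.50, tolerance = 0.01)
})

test_that("a zero-thickness stack is the identity", {
  bl <- beamline(list(list(material = "water", thickness_cm = 0)), 5)
  r <- energy_after_layers(bl)
  expect_identical(r$exit_energy, 5)
  expect_identical(r$energy_lost, 0)
})

test_that("a beam that cannot traverse a layer raises a stopped-in-layer error", {
  bl <- beamline(list(list(material = "water", thickness_cm = 1)), 7.5)
  expect_error(energy_after_layers(bl), "stopped in layer 1")
  expect_error(beamline(list(list(material = "lead", thickness_cm = 1)), 8),
               "no stopping-power table")
})

test_that("range-energy roundtrip: a slab of thickness R(E1)-R(E2) degrades E1 to E2 within 1%", {
  tab <- water_table()
  for (pair in list(c(8, 7.5), c(7.5, 5), c(5, 2.6), c(10, 3))) {
    slab <- csda_range(tab, pair[1]) - csda_range(tab, pair[2])
    bl <- beamline(list(list(material = "water", thickness_cm = slab)),
                   pair[1], tables = list(water = tab))
    expect_equal(energy_after_layers(bl)$exit_energy, pair[2],
                 tolerance = 0.01)
  }
})
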