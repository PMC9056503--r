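test_that("packaged isotope constants satisfy their invariants and round-trip through JSON", {
  iso <- isotopes()
  expect_equal(iso$lambda_per_min * iso$half_life_min, rep(log(2), 3))
  expect_true(all(iso$threshold_MeV < 7.5))
  expect_equal(iso["F18", "half_life_min"], 109.77)
  expect_equal(iso["C11", "half_life_min"], 20.364)
  expect_equal(iso["N13", "half_life_min"], 9.965)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(iso, f, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$half_life_min, iso$half_life_min)
  expect_identical(back$integrated_xs_mb_MeV, iso$integrated_xs_mb_MeV)
})

test_that("atom densities follow the closed form", {
  w <- tissue_composition("water")
  n <- atoms_per_gram(w)
  expect_equal(n[["N_O"]], 0.888 * 6.02214076e23 / 16)
  expect_equal(n[["N_N"]], 0)
  scc <- tissue_composition("squamous_cell_carcinoma")
  ns <- atoms_per_gram(scc)
  expect_equal(ns[["N_O"]] / ns[["N_N"]], (0.650 / 16) / (0.048 / 14),
               tolerance = 1e-12)
})

test_that("composition validation enforces the mass-fraction invariants", {
  expect_error(tissue_composition(H = 0.5, C = 0.1, N = 0.1, O = 0.1),
               "sum to")
  expect_error(tissue_composition(H = 0.1, C = 0.2, N = 0.05, O = 0.65,
                                  f18O = 1.2), "f18O")
  expect_error(tissue_composition("gelatin"), "unknown composition preset")
})

test_that("activation yields vanish in the right limits and follow the yield expressions", {
  c0 <- tissue_composition("squamous_cell_carcinoma", f18O = 0)
  expect_equal(relative_yields(c0)[["A_18F"]], 0)
  c1 <- tissue_composition(H = 0.098, C = 0.195, N = 0.048, O = 0.650, f18O = 1)
  expect_equal(relative_yields(c1)[["A_13N"]], 0)
  c3 <- tissue_composition(H = 0.098, C = 0.195, N = 0.048, O = 0.650, f18O = 0.03)
  y <- relative_yields(c3)
  n <- atoms_per_gram(c3)
  expect_equal(y[["A_18F"]] / y[["A_11C"]],
               (n[["N_O"]] * 0.03 * 1130.71) / (n[["N_N"]] * 75.1),
               tolerance = 1e-12)
  # yields scale linearly in the normalisation constant
  expect_equal(relative_yields(c3, A0 = 2.5), 2.5 * y)
})

test_that("yields outside the packaged energy domain are refused", {
  comp <- tissue_composition("squamous_cell_carcinoma", f18O = 0.03)
  expect_error(relative_yields(comp, Ep = 8), "valid only at Ep = 7.5")
  expect_error(relative_yields(comp, Ep = 17), "15O")
  expect_silent(relative_yields(comp, Ep = 8,
                                user_integrals = c(C11 = 80, N13 = 60, F18 = 1200)))
})

test_that("the expected 13N/11C ratio behaves in both conventions", {
  expect_identical(expected_ratio_13N_11C(0), 0.394)
  expect_equal(expected_ratio_13N_11C(0.5), 0.197)
  expect_equal(expected_ratio_13N_11C(1), 0)
  expect_equal(expected_ratio_13N_11C(1, mode = "xs_integral"), 0)
  # the transparent cross-section ratio is far larger than the calibrated constant
  expect_gt(expected_ratio_13N_11C(0, mode = "xs_integral"), 5)
  # strictly decreasing in f
  f <- seq(0, 1, by = 0.1)
  expect_true(all(diff(expected_ratio_13N_11C(f)) < 0))
  expect_error(expected_ratio_13N_11C(1.5), "f18O")
})

test_that("enrichment inference inverts the yield expressions exactly", {
  comp <- tissue_composition(H = 0.098, C = 0.195, N = 0.048, O = 0.650,
                             f18O = 0.03)
  y <- relative_yields(comp)
  f <- infer_f18O(y[["A_18F"]], y[["A_11C"]], comp)
  expect_equal(f$f18O, 0.03, tolerance = 1e-12)
  expect_false(f$clipped)
  expect_equal(infer_f18O(0, y[["A_11C"]], comp)$f18O, 0)
  expect_error(infer_f18O(1, 0, comp), "A_11C")
  big <- infer_f18O(1e6 * y[["A_18F"]], y[["A_11C"]], comp)
  expect_true(big$clipped)
  expect_identical(big$f18O, 1)
})

test_that("inference uncertainty matches a Monte Carlo oracle", {
  comp <- tissue_composition(H = 0.098, C = 0.195, N = 0.048, O = 0.650,
                             f18O = 0.03)
  y <- relative_yields(comp)
  set.seed(99)
  n <- 1000
  fs <- vapply(seq_len(n), function(i)
    infer_f18O(y[["A_18F"]] * (1 + rnorm(1, 0, 0.05)),
               y[["A_11C"]] * (1 + rnorm(1, 0, 0.05)), comp)$f18O,
    numeric(1))
  expect_equal(mean(fs), 0.03, tolerance = 0.01)
  prop <- infer_f18O(y[["A_18F"]], y[["A_11C"]], comp,
                     rel_unc = c(A_18F = 0.05, A_11C = 0.05))$se
  expect_equal(sd(fs), prop, tolerance = 0.20)
})

test_that("the activity convention rescales yields by the decay constants and still round-trips", {
  comp <- tissue_composition(H = 0.098, C = 0.195, N = 0.048, O = 0.650,
                             f18O = 0.02)
  yp <- relative_yields(comp)
  ya <- relative_yields(comp, convention = "activity")
  iso <- isotopes()
  expect_equal(ya[["A_18F"]] / yp[["A_18F"]], iso["F18", "lambda_per_min"])
  expect_equal(ya[["A_11C"]] / yp[["A_11C"]], iso["C11", "lambda_per_min"])
  # inference in the matching convention inverts exactly
  f <- infer_f18O(ya[["A_18F"]], ya[["A_11C"]], comp,
                  convention = "activity")
  expect_equal(f$f18O, 0.02, tolerance = 1e-12)
  # mixing conventions rescales the inferred fraction by the lambda ratio
  fmix <- infer_f18O(yp[["A_18F"]], yp[["A_11C"]], comp,
                     convention = "activity")
  expect_equal(fmix$f18O / 0.02,
               iso["C11", "lambda_per_min"] / iso["F18", "lambda_per_min"],
               tolerance = 1e-9)
})

test_that("the Bragg-peak activity estimator is zero at zero dose and linear in enrichment", {
  expect_identical(predict_bp_activity(0, 0.3), 0)
  a1 <- predict_bp_activity(2, 0.15)
  a2 <- predict_bp_activity(2, 0.30)
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
  expect_equal(predict_bp_activity(4, 0.3), 2 * a2, tolerance = 1e-12)
  expect_error(predict_bp_activity(2, 1.5), "enrichment")
})
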