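test_that("scenario presets encode the study conditions and pass the spec invariants", {
  fs <- vapply(c("T1", "T2", "T3", "T4"), function(nm)
    paper_scenario(nm)$f18O, numeric(1))
  expect_equal(unname(fs[c("T1", "T4")]), c(0.0061, 0.030))
  expect_true(all(fs >= 0.0061 & fs <= 0.030))
  for (nm in c("T1", "T2", "T3", "T4", "E1", "E2")) {
    s <- paper_scenario(nm)
    expect_s3_class(s, "scenario_spec")
    expect_equal(s$pre$duration_min, 29)
    expect_equal(s$post$duration_min, 22)
    expect_equal(unname(s$retention["F18"]), 0.59)
    # amplitude truths are consistent with the analysis conventions
    expect_equal(s$amplitudes[["N13"]] / s$amplitudes[["C11"]],
                 (1 - s$f18O) * 0.394, tolerance = 1e-12)
  }
  e1 <- paper_scenario("E1")$tac_spec
  expect_equal(e1$n_frames, 9L)
  expect_equal(e1$frame_min, 60)
  expect_true(e1$start_min >= 210 && e1$start_min <= 240)
  expect_length(paper_scenario("T3")$gaps_pre, 1)
})

test_that("an empty scenario produces an empty event stream", {
  s <- scenario_spec(c(F18 = 0, C11 = 0, N13 = 0), f18O = 0,
                     background_rate = 0)
  ev <- simulate_event_stream(s, "pre")
  expect_length(ev$t_s, 0)
})

test_that("event counts match the analytic Poisson integral within 4 sigma", {
  A <- 50
  s <- scenario_spec(c(F18 = A, C11 = 0, N13 = 0), f18O = 0,
                     background_rate = 0,
                     pre = list(start_min = 0, duration_min = 120))
  l <- lam_s()[["F18"]]
  Lam <- A / l * (1 - exp(-l * 120 * 60))
  ev <- simulate_event_stream(s, "pre", seed = 17)
  expect_lt(abs(length(ev$t_s) - Lam), 4 * sqrt(Lam))
})

test_that("generators are pure functions of (spec, seed)", {
  s <- paper_scenario("T2")
  expect_identical(simulate_event_stream(s, "pre", seed = 3),
                   simulate_event_stream(s, "pre", seed = 3))
  expect_identical(simulate_count_series(s, "post", seed = 4),
                   simulate_count_series(s, "post", seed = 4))
  expect_identical(simulate_tac(paper_scenario("E1"), seed = 5),
                   simulate_tac(paper_scenario("E1"), seed = 5))
  expect_identical(simulate_spot_image(0.8, 0.9, snr = 10, seed = 6),
                   simulate_spot_image(0.8, 0.9, snr = 10, seed = 6))
  expect_false(identical(simulate_event_stream(s, "pre", seed = 3),
                         simulate_event_stream(s, "pre", seed = 4)))
})

test_that("event times follow the exponential intensity (time-rescaling KS test)", {
  A <- 80
  s <- scenario_spec(c(F18 = 0, C11 = A, N13 = 0), f18O = 0,
                     background_rate = 0,
                     pre = list(start_min = 5, duration_min = 60))
  ev <- simulate_event_stream(s, "pre", seed = 23)
  l <- lam_s()[["C11"]]
  t0 <- 5 * 60; t1 <- t0 + 60 * 60
  tt <- ev$t_s + t0
  u <- (exp(-l * t0) - exp(-l * tt)) / (exp(-l * t0) - exp(-l * t1))
  # float rounding can duplicate a transformed value; the tie warning is moot
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("post-wash streams carry the retention truth", {
  s <- paper_scenario("T4")
  post <- simulate_count_series(s, "post", seed = 31)
  tr <- attr(post, "truth")$amplitudes
  expect_equal(unname(tr["F18"]), unname(s$amplitudes["F18"] * 0.59))
  expect_equal(unname(tr["C11"]), unname(s$amplitudes["C11"] * 0.14))
})

test_that("the noiseless TAC equals the model frame integrals exactly", {
  s <- paper_scenario("E1")
  curve <- simulate_tac(s, noise = FALSE)
  lam <- log(2) / 109.77 + log(2) / (14.7 * 60)
  mu <- 100 * (exp(-lam * curve$frame_start_min) -
                 exp(-lam * curve$frame_end_min)) / (lam * 60)
  expect_equal(curve$activity, mu, tolerance = 1e-12)
})

test_that("TAC noise realises the stated coefficient of variation", {
  s <- paper_scenario("E1")
  y <- vapply(seq_len(300), function(i)
    simulate_tac(s, seed = i)$activity[1], numeric(1))
  mu <- simulate_tac(s, noise = FALSE)$activity[1]
  expect_equal(sd(y) / mu, 0.03, tolerance = 0.10)
})

test_that("noiseless spot-image moments return the generating spreads exactly", {
  img <- simulate_spot_image(0.78, 0.89, pitch = 0.02)
  f <- fit_gaussian_spot(img, attr(img, "pitch"), method = "moments")
  expect_equal(f$sigma_x, 0.78, tolerance = 1e-4)
  expect_equal(f$sigma_y, 0.89, tolerance = 1e-4)
})

test_that("scenario validation enforces the rate and retention invariants", {
  expect_error(scenario_spec(c(F18 = -1, C11 = 0, N13 = 0), 0), ">= 0")
  expect_error(scenario_spec(c(F18 = 1, C11 = 1, N13 = 1), 0,
                             retention = c(F18 = 2, C11 = 0, N13 = 0)),
               "retention")
  expect_error(scenario_spec(c(F18 = 1, C11 = 1, N13 = 1), f18O = 2), "f18O")
})
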