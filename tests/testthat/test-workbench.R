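cfg_list <- function(...) structure(list(...), class = "run_config")

test_that("configurations are schema-validated with unknown keys rejected", {
  path <- system.file("extdata", "example_config.yaml", package = "petrv")
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_match(attr(cfg, "md5"), "^[0-9a-f]{32}$")
  bad <- tempfile(fileext = ".yaml")
  writeLines("typo_key: 1", bad)
  expect_error(read_run_config(bad), "unknown config key")
  writeLines(c("plan:", "  sigma_q_mm: 1"), bad)
  expect_error(read_run_config(bad), "unknown key\\(s\\) in 'plan'")
  expect_error(read_run_config(tempfile()), "not found")
})

test_that("the planning pipeline reproduces the plan numbers and its summary round-trips", {
  out <- tempfile()
  cfg <- cfg_list(seed = 1, output_dir = out,
                  plan = list(sigma_x_mm = 0.78, sigma_y_mm = 0.89))
  rep <- run_plan(cfg)
  expect_equal(rep$central_fluence_p_per_cm2, 2.5e13, tolerance = 0.05)
  expect_equal(rep$central_dose_gy, 2.4e5, tolerance = 0.05)
  expect_equal(rep$n_spots, 9L)
  back <- jsonlite::read_json(file.path(out, "plan_report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$central_fluence_p_per_cm2, rep$central_fluence_p_per_cm2)
  m <- read_map(file.path(out, "fluence_map.tsv"))
  expect_equal(max(m$values), rep$central_fluence_p_per_cm2, tolerance = 1e-3)
})

test_that("the ex-vivo pipeline recovers the scenario enrichment within its confidence interval", {
  out <- tempfile()
  cfg <- cfg_list(seed = 1, output_dir = out, exvivo = list(scenario = "T4"))
  rep <- suppressWarnings(run_exvivo(cfg))
  expect_true(abs(rep$f18O_percent - 3.0) <= 2 * rep$f18O_se_percent)
  ret <- rep$retention_percent[[1]]
  expect_equal(ret$isotope, "F18")
  expect_true(abs(ret$retention - 59) <= 3 * ret$se + 2)
  expect_true(file.exists(file.path(out, "exvivo_report.json")))
  # reproducibility: identical config and seed give identical reports
  rep2 <- suppressWarnings(run_exvivo(cfg))
  expect_identical(rep, rep2)
})

test_that("identical pre and post inputs yield unit retention through the pipeline", {
  spec <- paper_scenario("T2")
  ev <- simulate_event_stream(spec, "pre", seed = 7)
  res <- suppressWarnings(
    exvivo_analysis(ev, ev, background_rate = spec$background_rate))
  ok <- res$retention$defined
  expect_equal(res$retention$retention[ok],
               rep(1, sum(ok)), tolerance = 1e-9)
})

test_that("missing inputs produce clean validation errors", {
  expect_error(run_exvivo(cfg_list(exvivo = list())), "either 'scenario'")
  expect_error(run_exvivo(cfg_list(exvivo = list(
    pre_events = "a.csv", post_events = tempfile()))), "not found")
  expect_error(run_invivo(cfg_list(invivo = list())), "either 'scenario'")
  expect_error(run_plan(cfg_list(seed = 1)), "no 'plan' section")
})

test_that("the in-vivo pipeline reports half-lives with confidence intervals", {
  out <- tempfile()
  rep <- run_invivo(cfg_list(seed = 3, output_dir = out,
                             invivo = list(scenario = "E1")))
  expect_equal(rep$T_comb_min, 97.6, tolerance = 0.05)
  expect_length(rep$T_comb_ci_min, 2)
  expect_true(rep$T_comb_ci_min[1] < rep$T_comb_min &&
                rep$T_comb_min < rep$T_comb_ci_min[2])
  expect_true(is.numeric(rep$T_bio_h))
})

test_that("the command-line workbench runs the planning pipeline end to end", {
  exe <- system.file("exec", "petrv", package = "petrv")
  expect_true(nzchar(exe))
  out <- tempfile()
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c(sprintf("output_dir: %s", out), "plan:",
               "  sigma_x_mm: 0.78", "  sigma_y_mm: 0.89"), cfgf)
  st <- system2("Rscript", c(exe, "plan", "--config", cfgf),
                stdout = TRUE, stderr = TRUE)
  expect_identical(attr(st, "status"), NULL)  # exit 0
  expect_true(file.exists(file.path(out, "plan_report.json")))
  # validation failures exit with status 2
  st2 <- suppressWarnings(system2("Rscript",
                                  c(exe, "plan", "--config", tempfile()),
                                  stdout = TRUE, stderr = TRUE))
  expect_identical(attr(st2, "status"), 2L)
})
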