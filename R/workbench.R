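#' Read and validate a workbench run configuration
#'
#' Configurations are YAML (or JSON) mappings.  The schema is validated
#' before any computation: unknown keys are rejected, and each pipeline
#' section checks its required fields when used.
#'
#' @param path path to a YAML/JSON config file.
#' @return An object of class `run_config` (a named list with attribute
#'   `"md5"` carrying the file hash).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .validate_config(cfg)
  structure(cfg, md5 = unname(tools::md5sum(path)), class = "run_config")
}

.config_schema <- list(
  seed = NULL, output_dir = NULL,
  energy_window = c("centre_keV", "half_width", "convention"),
  bin_width_s = NULL,
  constraint = c("mode", "f18O", "ratio_constant"),
  composition = c("preset", "H", "C", "N", "O", "f18O"),
  plan = c("pitch_mm", "dwell_time_s", "current_nA", "entry_energy",
           "sigma_x_mm", "sigma_y_mm", "grid_pitch_mm", "grid_extent_mm",
           "slab_um"),
  exvivo = c("scenario", "pre_events", "post_events", "background_rate",
             "background_unc", "A_11C"),
  invivo = c("scenario", "tac", "isotope", "frame_integral", "conf")
)

.validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping")
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    allowed <- .config_schema[[k]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[k]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", k, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

.cfg_get <- function(cfg, key, default) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

.report_header <- function(cfg, seed) {
  list(package = "petrv", version = as.character(packageVersion("petrv")),
       config_md5 = if (is.null(attr(cfg, "md5"))) NA else attr(cfg, "md5"),
       seed = seed, time_origin = "end of irradiation")
}

.write_report <- function(report, cfg, filename) {
  outdir <- .cfg_get(cfg, "output_dir", ".")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outdir, filename)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  message("report written to ", path)
  invisible(path)
}

#' Planning pipeline: fluence and surface-dose maps
#'
#' Builds the spot plan described by the config's `plan` section, computes
#' the fluence and dose maps, writes them as delimited grids with JSON
#' sidecars plus a machine-readable summary JSON.
#'
#' @param cfg a [read_run_config()] result (or an equivalent list).
#' @return The report list, invisibly; files are written to
#'   `cfg$output_dir`.
#' @export
run_plan <- function(cfg) {
  .validate_config(unclass(cfg))
  p <- cfg$plan
  if (is.null(p)) stop("config has no 'plan' section")
  plan <- grid_plan_3x3(pitch_mm = .cfg_get(p, "pitch_mm", 1.2),
                        dwell_time_s = .cfg_get(p, "dwell_time_s", 10),
                        current_nA = .cfg_get(p, "current_nA", 6.0),
                        entry_energy = .cfg_get(p, "entry_energy", 7.5))
  sx <- .cfg_get(p, "sigma_x_mm", 0.78); sy <- .cfg_get(p, "sigma_y_mm", 0.89)
  gp <- .cfg_get(p, "grid_pitch_mm", 0.05)
  ge <- .cfg_get(p, "grid_extent_mm", 5)
  slab <- .cfg_get(p, "slab_um", 100)
  fm <- fluence_map(plan, sx, sy, pitch = gp, extent = ge)
  dm <- dose_map(plan, sx, sy, slab_um = slab, pitch = gp, extent = ge)
  outdir <- .cfg_get(cfg, "output_dir", ".")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_map(fm, file.path(outdir, "fluence_map.tsv"))
  write_map(dm, file.path(outdir, "dose_map.tsv"))
  centre <- fluence_at(plan, 0, 0, sx, sy)
  report <- c(.report_header(cfg, .cfg_get(cfg, "seed", NA)), list(
    pipeline = "plan",
    n_spots = nrow(plan),
    protons_per_spot = plan$protons[1],
    total_protons = sum(plan$protons),
    sigma_mm = list(x = sx, y = sy),
    central_fluence_p_per_cm2 = centre,
    central_dose_gy = surface_dose(centre, attr(plan, "entry_energy"), slab),
    max_dose_gy = max(dm$values),
    fluence_grid_integral_protons = map_integral(fm),
    units = list(fluence = "protons/cm^2", dose = "Gy",
                 averaging_depth_um = slab)))
  .write_report(report, cfg, "plan_report.json")
  invisible(report)
}

#' Ex-vivo spectrometry analysis pipeline
#'
#' The full inverse analysis on a pre-/post-wash pair of list-mode event
#' records: 511-keV windowing, binning and background subtraction,
#' constrained pre-wash triple-exponential fitting with the
#' \eqn{A_{13N}/A_{11C} = (1-f)\,0.394} tie, inference of the \eqn{^{18}}O
#' enrichment from the \eqn{^{18}}F/\eqn{^{11}}C amplitude ratio, a
#' constrained post-wash fit, and decay-corrected retention fractions.
#'
#' Because the constraint depends on the unknown enrichment only through the
#' weak factor \eqn{(1-f)}, the enrichment is obtained by a short fixed-point
#' iteration: fit with \eqn{f = 0}, infer \eqn{f} from the
#' \eqn{A_{18F}/A_{11C}} ratio, refit with the inferred value and infer
#' again.  An unconstrained pre-wash fit is also returned for comparison
#' (`pre_free`); its \eqn{^{11}}C amplitude is far noisier, which is exactly
#' why the a-priori ratio information enters the fit.
#'
#' @param pre_events,post_events [gamma_events()] records.
#' @param background_rate,background_unc in-window background (counts/s).
#' @param bin_width_s histogram bin width, s.
#' @param window an [energy_window()].
#' @param comp a [tissue_composition()] for the enrichment inference.
#' @param ratio_constant constraint constant.
#' @return A list with the four fits (`pre_free`, `pre`, `post`), the
#'   inferred `f18O`, and the `retention` table.
#' @export
exvivo_analysis <- function(pre_events, post_events, background_rate = 0,
                            background_unc = 0, bin_width_s = 10,
                            window = energy_window(),
                            comp = tissue_composition("squamous_cell_carcinoma"),
                            ratio_constant = 0.394) {
  prep <- function(ev) bin_and_subtract(window_counts(ev, window),
                                        bin_width_s = bin_width_s,
                                        background_rate = background_rate,
                                        background_unc = background_unc)
  s_pre <- prep(pre_events); s_post <- prep(post_events)
  fit_free <- fit_decay_triple(s_pre, constraint = "none")
  # fixed-point iteration on the weak (1 - f) dependence of the constraint
  infer_from <- function(fit) {
    se <- sqrt(diag(fit$vcov))
    infer_f18O(fit$amplitudes[["F18"]], fit$amplitudes[["C11"]], comp,
               rel_unc = c(A_18F = se[["F18"]] /
                             max(fit$amplitudes[["F18"]], 1e-12),
                           A_11C = se[["C11"]] /
                             max(fit$amplitudes[["C11"]], 1e-12)))
  }
  f0 <- infer_from(fit_decay_triple(s_pre, constraint = "ratio", f18O = 0,
                                    ratio_constant = ratio_constant))
  # both windows share the once-updated constraint so that identical inputs
  # give identical fits (and unit retention)
  fit_pre <- fit_decay_triple(s_pre, constraint = "ratio", f18O = f0$f18O,
                              ratio_constant = ratio_constant)
  f <- infer_from(fit_pre)
  fit_post <- fit_decay_triple(s_post, constraint = "ratio", f18O = f0$f18O,
                               ratio_constant = ratio_constant)
  ret <- retention_fractions(fit_pre, fit_post)
  list(pre_free = fit_free, pre = fit_pre, post = fit_post,
       f18O = f, retention = ret)
}

#' Ex-vivo pipeline from a config
#'
#' Runs [exvivo_analysis()] on either event files named in the config
#' (`pre_events` / `post_events`) or a simulated packaged scenario
#' (`scenario: T1..T4`), and writes a JSON report with amplitudes,
#' covariance, the inferred enrichment, retention and goodness of fit.
#'
#' @inheritParams run_plan
#' @return The report list, invisibly.
#' @export
run_exvivo <- function(cfg) {
  .validate_config(unclass(cfg))
  ex <- cfg$exvivo
  if (is.null(ex)) stop("config has no 'exvivo' section")
  seed <- .cfg_get(cfg, "seed", 1)
  if (!is.null(ex$scenario)) {
    spec <- paper_scenario(ex$scenario,
                           A_11C = .cfg_get(ex, "A_11C", 40))
    pre <- simulate_event_stream(spec, "pre", seed = seed)
    post <- simulate_event_stream(spec, "post", seed = seed + 1)
    bg <- spec$background_rate
  } else {
    if (is.null(ex$pre_events) || is.null(ex$post_events))
      stop("exvivo config needs either 'scenario' or both 'pre_events' and 'post_events'")
    pre <- read_events(ex$pre_events)
    post <- read_events(ex$post_events)
    bg <- .cfg_get(ex, "background_rate", 0)
  }
  wcfg <- .cfg_get(cfg, "energy_window", list())
  window <- energy_window(centre_keV = .cfg_get(wcfg, "centre_keV", 511),
                          half_width = .cfg_get(wcfg, "half_width", 0.10),
                          convention = .cfg_get(wcfg, "convention", "half_width"))
  ccfg <- .cfg_get(cfg, "composition", list(preset = "squamous_cell_carcinoma"))
  comp <- if (!is.null(ccfg$preset)) tissue_composition(ccfg$preset)
          else tissue_composition(H = ccfg$H, C = ccfg$C, N = ccfg$N, O = ccfg$O)
  res <- exvivo_analysis(pre, post,
                         background_rate = bg,
                         background_unc = .cfg_get(ex, "background_unc", 0),
                         bin_width_s = .cfg_get(cfg, "bin_width_s", 10),
                         window = window, comp = comp,
                         ratio_constant = .cfg_get(
                           .cfg_get(cfg, "constraint", list()),
                           "ratio_constant", 0.394))
  if (any(res$pre$at_bound) || any(res$post$at_bound))
    warning("some fitted amplitudes are at the zero bound")
  if (res$f18O$clipped) warning("inferred f18O was clipped to [0, 1]")
  fitjson <- function(f) list(
    amplitudes_cps = as.list(f$amplitudes),
    se_cps = as.list(sqrt(diag(f$vcov))),
    covariance = unname(apply(f$vcov, 1, as.list)),
    at_bound = as.list(f$at_bound),
    constraint = f$constraint, chisq = f$chisq, dof = f$dof)
  report <- c(.report_header(cfg, seed), list(
    pipeline = "exvivo",
    pre_fit = fitjson(res$pre), post_fit = fitjson(res$post),
    f18O_percent = res$f18O$f18O_percent,
    f18O_se_percent = 100 * res$f18O$se,
    retention_percent = lapply(rownames(res$retention), function(nm)
      list(isotope = nm, retention = 100 * res$retention[nm, "retention"],
           se = 100 * res$retention[nm, "se"],
           defined = res$retention[nm, "defined"])),
    units = list(amplitudes = "counts/s at end of irradiation",
                 retention = "percent", f18O = "percent")))
  .write_report(report, cfg, "exvivo_report.json")
  invisible(report)
}

#' In-vivo washout pipeline from a config
#'
#' Fits the physical-times-biological washout model to a PET time-activity
#' curve named in the config (`tac:` CSV path) or simulated from a packaged
#' dynamic scenario (`scenario: E1|E2`), and writes a JSON half-life report.
#'
#' @inheritParams run_plan
#' @return The report list, invisibly.
#' @export
run_invivo <- function(cfg) {
  .validate_config(unclass(cfg))
  iv <- cfg$invivo
  if (is.null(iv)) stop("config has no 'invivo' section")
  seed <- .cfg_get(cfg, "seed", 1)
  curve <- if (!is.null(iv$scenario))
    simulate_tac(paper_scenario(iv$scenario), seed = seed)
  else if (!is.null(iv$tac)) read_tac(iv$tac)
  else stop("invivo config needs either 'scenario' or 'tac'")
  fit <- fit_washout(curve,
                     isotope = .cfg_get(iv, "isotope", "F18"),
                     frame_integral = .cfg_get(iv, "frame_integral", TRUE),
                     conf = .cfg_get(iv, "conf", 0.95))
  report <- c(.report_header(cfg, seed), list(
    pipeline = "invivo",
    n_frames = nrow(curve),
    A0 = fit$A0,
    washout_detected = fit$washout_detected,
    T_comb_min = fit$T_comb_min,
    T_comb_ci_min = fit$T_comb_ci_min,
    T_bio_h = if (is.finite(fit$T_bio_h)) fit$T_bio_h else "no detectable washout",
    T_bio_ci_h = fit$T_bio_ci_h,
    conf = fit$conf,
    units = list(T_comb = "min", T_bio = "h",
                 time_origin = "end of irradiation")))
  .write_report(report, cfg, "invivo_report.json")
  invisible(report)
}
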