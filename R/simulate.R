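#' Synthetic measurement scenario
#'
#' Ground-truth description of one simulated irradiation experiment: the
#' per-isotope count-rate amplitudes at the end of irradiation, the
#' \eqn{^{18}}O enrichment, the in-window background rate, the pre-/post-wash
#' counting windows, the per-isotope washing retention, and (for dynamic PET
#' scenarios) the frame structure and noise of the time-activity curve.
#'
#' @param amplitudes named numeric `c(F18 =, C11 =, N13 =)`, counts/s at the
#'   end of irradiation (detected, in-window).
#' @param f18O true enrichment fraction.
#' @param background_rate in-window background, counts/s.
#' @param pre,post lists `list(start_min =, duration_min =)` for the two
#'   counting windows (minutes after end of irradiation).
#' @param retention named retention fractions in `[0, 1]` applied to the
#'   amplitudes for the post-wash window.
#' @param gaps_pre list of `c(start, end)` live-time gaps (s, acquisition
#'   clock) in the pre-wash measurement.
#' @param tac_spec list `list(n_frames =, frame_min =, start_min =, cv =,
#'   A0 =, T_bio_h =)` for dynamic PET scenarios, or `NULL`.
#' @param seed default RNG seed used by the generators.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(amplitudes, f18O, background_rate = 1,
                          pre = list(start_min = 10, duration_min = 29),
                          post = list(start_min = 50, duration_min = 22),
                          retention = c(F18 = 0.59, C11 = 0.14, N13 = 0.14),
                          gaps_pre = list(), tac_spec = NULL, seed = 1) {
  stopifnot(all(c("F18", "C11", "N13") %in% names(amplitudes)))
  if (any(amplitudes < 0) || background_rate < 0) stop("rates must be >= 0")
  if (any(retention < 0 | retention > 1)) stop("retention must lie in [0, 1]")
  if (f18O < 0 || f18O > 1) stop("f18O must lie in [0, 1]")
  if (pre$duration_min <= 0 || post$duration_min <= 0)
    stop("window durations must be > 0")
  structure(list(amplitudes = amplitudes[c("F18", "C11", "N13")], f18O = f18O,
                 background_rate = background_rate, pre = pre, post = post,
                 retention = retention, gaps_pre = gaps_pre,
                 tac_spec = tac_spec, seed = seed),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> f18O = %.3g%%, amplitudes (cps at end of irradiation):\n",
              100 * x$f18O))
  cat(sprintf("  F18 %.4g, C11 %.4g, N13 %.4g; background %.3g cps\n",
              x$amplitudes["F18"], x$amplitudes["C11"], x$amplitudes["N13"],
              x$background_rate))
  cat(sprintf("  pre-wash %g+%g min, post-wash %g+%g min, retention F18 %.2f / others %.2f\n",
              x$pre$start_min, x$pre$duration_min, x$post$start_min,
              x$post$duration_min, x$retention["F18"], x$retention["C11"]))
  if (!is.null(x$tac_spec))
    cat(sprintf("  TAC: %d x %g-min frames from %g min, CV %.3g, T_bio %.3g h\n",
                x$tac_spec$n_frames, x$tac_spec$frame_min,
                x$tac_spec$start_min, x$tac_spec$cv, x$tac_spec$T_bio_h))
  invisible(x)
}

#' Packaged measurement scenarios
#'
#' Presets emulating the study conditions of the modelled experiments.
#' `T1`-`T4` are ex-vivo counting scenarios: 29-min pre-wash measurement
#' starting 10 min after irradiation, 22-min post-wash measurement starting
#' 50 min after irradiation, enrichment from 0.61% (`T1`) to 3.0% (`T4`),
#' retention 0.59 for \eqn{^{18}}F and 0.14 for the other isotopes, 1 cps
#' in-window background; `T3` additionally carries a 10-min acquisition gap.
#' `E1`/`E2` are dynamic PET scenarios with nine 60-min frames starting
#' 3.5-4 h after irradiation and biological half-lives of 14.7 h and 21 h.
#'
#' Amplitudes are internally consistent: \eqn{A_{13N}/A_{11C} =
#' (1-f)\cdot0.394} (the calibrated constraint constant) and
#' \eqn{A_{18F}/A_{11C}} follows the activation yield expressions at the
#' preset enrichment.  The absolute scale (tens of counts/s for
#' \eqn{^{11}}C) is a calibration choice made so that fit uncertainties
#' resemble the precision pattern of the modelled experiments; see the
#' vignette.
#'
#' @param name one of `"T1"`, `"T2"`, `"T3"`, `"T4"`, `"E1"`, `"E2"`.
#' @param A_11C amplitude scale: the \eqn{^{11}}C count rate at the end of
#'   irradiation, counts/s.
#' @return A [scenario_spec()].
#' @export
paper_scenario <- function(name = c("T1", "T2", "T3", "T4", "E1", "E2"),
                           A_11C = 40) {
  name <- match.arg(name)
  f <- switch(name, T1 = 0.0061, T2 = 0.012, T3 = 0.020, T4 = 0.030,
              E1 = 0.030, E2 = 0.030)
  iso <- isotopes()
  nd <- atoms_per_gram(tissue_composition("squamous_cell_carcinoma"))
  k18 <- (nd[["N_O"]] / nd[["N_N"]]) *
    (iso["F18", "integrated_xs_mb_MeV"] / iso["C11", "integrated_xs_mb_MeV"])
  amps <- c(F18 = k18 * f * A_11C, C11 = A_11C,
            N13 = 0.394 * (1 - f) * A_11C)
  tspec <- if (name %in% c("E1", "E2"))
    list(n_frames = 9L, frame_min = 60,
         start_min = if (name == "E1") 225 else 210,
         cv = 0.03, A0 = 100,
         T_bio_h = if (name == "E1") 14.7 else 21)
  scenario_spec(amplitudes = amps, f18O = f,
                gaps_pre = if (name == "T3") list(c(600, 1200)) else list(),
                tac_spec = tspec,
                seed = match(name, c("T1", "T2", "T3", "T4", "E1", "E2")))
}

# photopeak width: 6% FWHM at 662 keV, resolution scaling as 1/sqrt(E)
.photopeak_sd <- function(E_keV = 511) {
  0.06 * sqrt(662 * E_keV) / (2 * sqrt(2 * log(2)))
}

# energy band over which the flat background is simulated [keV]
.bg_band <- c(300, 700)

# window-phase amplitudes: post-wash applies the retention truth
.phase_amplitudes <- function(spec, phase) {
  if (phase == "post") spec$amplitudes * spec$retention[names(spec$amplitudes)]
  else spec$amplitudes
}

#' Simulate a list-mode gamma event stream
#'
#' Draws event times as an inhomogeneous Poisson process for each decaying
#' isotope by inverse-CDF sampling of the exponential intensity
#' (time-rescaling), photopeak energies as a Gaussian at 511 keV with the
#' detector's 6%-at-662-keV resolution scaled as \eqn{1/\sqrt{E}}, and a
#' flat background over the 300-700 keV band whose rate is set so that the
#' in-window (511 keV +- 10%) background equals the scenario's
#' `background_rate`.  Events inside declared live-time gaps are dropped.
#' The output is a pure function of `(spec, phase, seed)`.
#'
#' @param spec a [scenario_spec()].
#' @param phase `"pre"` or `"post"` wash window.
#' @param seed RNG seed (defaults to the scenario seed).
#' @return A [gamma_events()] with the ground truth attached as attribute
#'   `"truth"`.
#' @export
simulate_event_stream <- function(spec, phase = c("pre", "post"),
                                  seed = spec$seed) {
  phase <- match.arg(phase)
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  win <- if (phase == "pre") spec$pre else spec$post
  t0 <- win$start_min * 60; t1 <- t0 + win$duration_min * 60
  amps <- .phase_amplitudes(spec, phase)
  lam_s <- setNames(isotopes()$lambda_per_min / 60, isotopes()$name)
  tt <- numeric(0); ee <- numeric(0)
  for (nm in names(amps)) {
    A <- amps[[nm]]; l <- lam_s[[nm]]
    if (A <= 0) next
    Lam <- A / l * (exp(-l * t0) - exp(-l * t1))
    n <- rpois(1, Lam)
    if (n == 0) next
    u <- runif(n)
    ts <- -log(exp(-l * t0) - u * (exp(-l * t0) - exp(-l * t1))) / l
    tt <- c(tt, ts - t0)
    ee <- c(ee, rnorm(n, 511, .photopeak_sd()))
  }
  if (spec$background_rate > 0) {
    ew <- energy_window()
    band_rate <- spec$background_rate * diff(.bg_band) / (ew$hi - ew$lo)
    nb <- rpois(1, band_rate * (t1 - t0))
    if (nb > 0) {
      tt <- c(tt, runif(nb, 0, t1 - t0))
      ee <- c(ee, runif(nb, .bg_band[1], .bg_band[2]))
    }
  }
  gaps <- if (phase == "pre") spec$gaps_pre else list()
  if (length(tt)) {
    keep <- rep(TRUE, length(tt))
    for (g in gaps) keep <- keep & !(tt >= g[1] & tt < g[2])
    o <- order(tt[keep])
    tt <- tt[keep][o]; ee <- pmax(ee[keep][o], 1e-6)
  }
  ev <- gamma_events(tt, ee, start_min = win$start_min, gaps = gaps,
                     duration_s = win$duration_min * 60)
  attr(ev, "truth") <- list(amplitudes = amps, f18O = spec$f18O,
                            background_rate = spec$background_rate,
                            phase = phase, seed = seed)
  ev
}

#' Simulate a binned in-window count series directly
#'
#' Fast generator for replicate studies: draws per-bin Poisson counts with
#' mean equal to the bin-integrated three-isotope model plus background (no
#' event-level simulation, no energy dimension).  Bins overlapping a
#' declared gap are masked and zeroed.
#'
#' @inheritParams simulate_event_stream
#' @param bin_width_s histogram bin width, s.
#' @param noise draw Poisson counts (default); `noise = FALSE` returns the
#'   exact expected-value series (noiseless model data).
#' @return A [count_series()] with attribute `"truth"`.
#' @export
simulate_count_series <- function(spec, phase = c("pre", "post"),
                                  seed = spec$seed, bin_width_s = 10,
                                  noise = TRUE) {
  phase <- match.arg(phase)
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  win <- if (phase == "pre") spec$pre else spec$post
  off <- win$start_min * 60
  n_bins <- ceiling(win$duration_min * 60 / bin_width_s)
  e <- off + seq(0, n_bins * bin_width_s, by = bin_width_s)
  t1 <- e[-length(e)]; t2 <- e[-1]
  amps <- .phase_amplitudes(spec, phase)
  lam_s <- setNames(isotopes()$lambda_per_min / 60, isotopes()$name)
  mu <- spec$background_rate * bin_width_s
  for (nm in names(amps))
    mu <- mu + amps[[nm]] / lam_s[[nm]] *
      (exp(-lam_s[[nm]] * t1) - exp(-lam_s[[nm]] * t2))
  raw <- if (noise) rpois(length(mu), mu) else mu
  masked <- rep(FALSE, length(raw))
  gaps <- if (phase == "pre") spec$gaps_pre else list()
  for (g in gaps)
    masked <- masked | (t1 - off < g[2] & t2 - off > g[1])
  raw[masked] <- 0
  cs <- count_series(t1, t2, raw, background_rate = spec$background_rate,
                     background_unc = 0, masked = masked,
                     check_integer = noise)
  attr(cs, "truth") <- list(amplitudes = amps, f18O = spec$f18O, phase = phase,
                            seed = seed)
  cs
}

#' Simulate a dynamic PET time-activity curve
#'
#' Frame-integrated \eqn{A_0 e^{-(\lambda_{phys}+\lambda_{bio}) t}} plus
#' Gaussian noise at the stated coefficient of variation.
#'
#' @param spec a [scenario_spec()] with a non-`NULL` `tac_spec`.
#' @param seed RNG seed.
#' @param noise simulate noise (set `FALSE` for the exact model integrals).
#' @return A [tac()] with attribute `"truth"`.
#' @export
simulate_tac <- function(spec, seed = spec$seed, noise = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  ts <- spec$tac_spec
  if (is.null(ts)) stop("scenario has no TAC specification")
  set.seed(seed)
  lam <- decay_constant("F18") + log(2) / (ts$T_bio_h * 60)  # 1/min
  e <- ts$start_min + seq(0, ts$n_frames * ts$frame_min, by = ts$frame_min)
  t1 <- e[-length(e)]; t2 <- e[-1]
  mu <- ts$A0 * (exp(-lam * t1) - exp(-lam * t2)) / (lam * (t2 - t1))
  y <- if (noise && ts$cv > 0) mu + rnorm(length(mu), 0, ts$cv * mu) else mu
  out <- tac(t1, t2, y, sd = if (noise && ts$cv > 0) ts$cv * mu else 0)
  attr(out, "truth") <- list(A0 = ts$A0, T_bio_h = ts$T_bio_h,
                             T_comb_min = combined_half_life(
                               109.77, ts$T_bio_h * 60),
                             cv = ts$cv, seed = seed)
  out
}

#' Simulate a film-like beam-spot image
#'
#' Samples a single 2-D Gaussian of spreads `sigma_x`, `sigma_y` (mm) on a
#' pixel grid, optionally adding Gaussian noise at the stated peak
#' signal-to-noise ratio.
#'
#' @param sigma_x,sigma_y Gaussian spreads in mm.
#' @param pitch pixel pitch in mm.
#' @param snr peak amplitude over noise standard deviation; `Inf` for a
#'   noiseless image.
#' @param seed RNG seed.
#' @param amplitude peak intensity.
#' @param half_extent image half-size in mm (default 5 sigma).
#' @return A numeric matrix (attribute `"pitch"` carries the pitch, attribute
#'   `"truth"` the parameters).
#' @export
simulate_spot_image <- function(sigma_x, sigma_y, pitch = 0.05, snr = Inf,
                                seed = 1, amplitude = 1000,
                                half_extent = 5 * max(sigma_x, sigma_y)) {
  set.seed(seed)
  n <- 2L * ceiling(half_extent / pitch) + 1L
  c0 <- (n - 1) / 2 * pitch
  x <- (seq_len(n) - 1) * pitch - c0
  img <- amplitude * outer(exp(-x^2 / (2 * sigma_x^2)),
                           exp(-x^2 / (2 * sigma_y^2)))
  if (is.finite(snr))
    img <- pmax(img + rnorm(length(img), 0, amplitude / snr), 0)
  attr(img, "pitch") <- pitch
  attr(img, "truth") <- list(sigma_x = sigma_x, sigma_y = sigma_y,
                             centre = c(c0, c0), snr = snr, seed = seed)
  img
}
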