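#' Packaged PET isotope constants
#'
#' The three positron emitters relevant to proton activation of
#' \eqn{^{18}}O-enriched tissue below 7.5 MeV, with half-lives, production
#' channels, reaction thresholds and integrated cross sections
#' \eqn{\int_0^{E_p}\sigma(E)\,dE} evaluated at \eqn{E_p = 7.5} MeV.
#' Constants are shipped as a JSON resource and parsed on demand; decay
#' constants are derived as \eqn{\lambda = \ln 2 / T_{1/2}}.
#'
#' @param names optional subset, e.g. `c("F18", "C11")`.
#' @return A data.frame with one row per isotope: `name`, `half_life_min`,
#'   `lambda_per_min`, `reaction_channel`, `threshold_MeV`,
#'   `integrated_xs_mb_MeV`, `target_element`.
#' @export
isotopes <- function(names = c("C11", "N13", "F18")) {
  path <- system.file("extdata", "isotopes.json", package = "petrv",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  rows <- lapply(raw$isotopes[names], function(r)
    data.frame(name = r$name, half_life_min = r$half_life_min,
               lambda_per_min = log(2) / r$half_life_min,
               reaction_channel = r$reaction_channel,
               threshold_MeV = r$threshold_MeV,
               integrated_xs_mb_MeV = r$integrated_xs_mb_MeV,
               target_element = r$target_element,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- out$name
  out
}

#' Decay constant of a packaged isotope
#'
#' @param isotope isotope name (`"F18"`, `"C11"`, `"N13"`).
#' @param per `"min"` or `"s"`.
#' @return \eqn{\lambda = \ln 2/T_{1/2}} in 1/min or 1/s.
#' @export
decay_constant <- function(isotope, per = c("min", "s")) {
  per <- match.arg(per)
  l <- isotopes(isotope)$lambda_per_min
  if (per == "s") l / 60 else l
}

#' Tissue elemental composition
#'
#' Mass fractions of H, C, N, O of the target tissue plus the fraction
#' `f18O` of oxygen atoms replaced by \eqn{^{18}}O.  The packaged presets are
#' `"squamous_cell_carcinoma"` (H 9.8%, C 19.5%, N 4.8%, O 65.0%; the
#' fractions sum to 99.1%, trace elements are ignored) and `"water"`.
#'
#' @param preset preset name, or `NULL` when fractions are given explicitly.
#' @param H,C,N,O mass fractions in `[0, 1]`; their sum must lie in
#'   `[0.95, 1.05]`.
#' @param f18O fraction of oxygen atoms that are \eqn{^{18}}O, in `[0, 1]`.
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(preset = NULL, H = NULL, C = NULL, N = NULL,
                               O = NULL, f18O = 0) {
  if (!is.null(preset)) {
    p <- switch(preset,
      squamous_cell_carcinoma = list(H = 0.098, C = 0.195, N = 0.048, O = 0.650),
      water = list(H = 0.112, C = 0, N = 0, O = 0.888),
      stop("unknown composition preset: ", preset))
    H <- p$H; C <- p$C; N <- p$N; O <- p$O
  }
  fr <- c(H = H, C = C, N = N, O = O)
  if (any(fr < 0 | fr > 1)) stop("mass fractions must lie in [0, 1]")
  if (sum(fr) < 0.95 || sum(fr) > 1.05)
    stop(sprintf("mass fractions sum to %.3f, outside [0.95, 1.05]", sum(fr)))
  if (f18O < 0 || f18O > 1) stop("f18O must lie in [0, 1]")
  structure(list(mass_fractions = fr, f18O = f18O,
                 preset = if (is.null(preset)) NA_character_ else preset),
            class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  f <- x$mass_fractions
  cat(sprintf("<tissue_composition>%s H %.1f%% C %.1f%% N %.1f%% O %.1f%%, f(18O) = %.2f%%\n",
              if (is.na(x$preset)) "" else paste0(" [", x$preset, "]"),
              100 * f["H"], 100 * f["C"], 100 * f["N"], 100 * f["O"],
              100 * x$f18O))
  invisible(x)
}

#' Oxygen and nitrogen atom densities
#'
#' \eqn{N_X = w_X N_A / m_X} atoms per gram of tissue, with nominal integer
#' atomic masses (O: 16, N: 14) by default.
#'
#' @param comp a [tissue_composition()].
#' @param masses named list of atomic masses in g/mol.
#' @return Named numeric `c(N_O =, N_N =)` in atoms per gram.
#' @export
atoms_per_gram <- function(comp, masses = list(O = 16, N = 14)) {
  stopifnot(inherits(comp, "tissue_composition"))
  f <- comp$mass_fractions
  c(N_O = unname(f["O"]) * .const$avogadro / masses$O,
    N_N = unname(f["N"]) * .const$avogadro / masses$N)
}

#' Relative activation yields of the three isotopes
#'
#' Per-isotope production in units of the common normalisation constant
#' \eqn{A_0} (which absorbs dose, target mass and detector efficiency):
#' \deqn{A_{18F} = A_0 N_O f_{18O} \int_0^{E_p}\sigma_{^{18}O(p,n)}\,dE,\quad
#'       A_{13N} = A_0 N_O (1-f_{18O}) \int_0^{E_p}\sigma_{^{16}O(p,X)}\,dE,\quad
#'       A_{11C} = A_0 N_N \int_0^{E_p}\sigma_{^{14}N(p,X)}\,dE.}
#' The packaged cross-section integrals are valid only at
#' \eqn{E_p = 7.5} MeV; other energies require user-supplied integrals.
#' These expressions are proportional to the number of produced nuclei; see
#' the package vignette for the two possible activity conventions.
#'
#' @param comp a [tissue_composition()] (its `f18O` is used).
#' @param Ep incoming proton energy, MeV.
#' @param user_integrals optional named numeric of
#'   \eqn{\int_0^{E_p}\sigma\,dE} values in mb MeV, names `F18`, `N13`,
#'   `C11`, for use at `Ep != 7.5`.
#' @param A0 the normalisation constant (default 1).
#' @param convention `"production"` (the yield expressions as written,
#'   proportional to produced nuclei) or `"activity"` (each yield multiplied
#'   by its decay constant, proportional to the decay rate of the produced
#'   nuclei).  Downstream ratios accept the same switch.
#' @return Named numeric `c(A_18F =, A_13N =, A_11C =)` in units of `A0`.
#' @export
relative_yields <- function(comp, Ep = 7.5, user_integrals = NULL, A0 = 1,
                            convention = c("production", "activity")) {
  convention <- match.arg(convention)
  stopifnot(inherits(comp, "tissue_composition"))
  if (Ep >= 16.79)
    stop("Ep >= 16.79 MeV opens the 16O(p,X)15O channel, which this three-isotope model excludes")
  iso <- isotopes()
  if (is.null(user_integrals)) {
    if (!isTRUE(all.equal(Ep, 7.5, tolerance = 1e-9)))
      stop("the packaged cross-section integrals are valid only at Ep = 7.5 MeV; ",
           "supply 'user_integrals' for other energies")
    I <- setNames(iso$integrated_xs_mb_MeV, iso$name)
  } else {
    I <- unlist(user_integrals)[c("C11", "N13", "F18")]
    if (any(is.na(I))) stop("'user_integrals' must name C11, N13 and F18")
  }
  nd <- atoms_per_gram(comp)
  f <- comp$f18O
  lam <- if (convention == "activity")
    setNames(iso$lambda_per_min, iso$name)
  else c(F18 = 1, N13 = 1, C11 = 1)
  c(A_18F = A0 * nd[["N_O"]] * f * I[["F18"]] * lam[["F18"]],
    A_13N = A0 * nd[["N_O"]] * (1 - f) * I[["N13"]] * lam[["N13"]],
    A_11C = A0 * nd[["N_N"]] * I[["C11"]] * lam[["C11"]])
}

#' Expected 13N/11C activity ratio
#'
#' Two conventions are packaged.  `mc_constant` (the default used by the
#' decay-fit constraint) returns \eqn{(1-f_{18O})\cdot 0.394}, a calibrated
#' constant that embeds the transport weighting of a full Monte Carlo
#' simulation.  `xs_integral` returns the transparent ratio of the yield
#' expressions from the packaged cross-section integrals and the tissue
#' composition; the two conventions disagree strongly (the plain
#' cross-section ratio is about \eqn{8.4\,(1-f)}), see the vignette.
#'
#' @param f18O fraction of oxygen atoms replaced by \eqn{^{18}}O, in `[0,1]`.
#' @param mode `"mc_constant"` or `"xs_integral"`.
#' @param constant the calibrated constant for `mc_constant` mode.
#' @param comp composition used by `xs_integral` mode.
#' @return The expected ratio \eqn{A_{13N}/A_{11C}} (dimensionless).
#' @export
expected_ratio_13N_11C <- function(f18O, mode = c("mc_constant", "xs_integral"),
                                   constant = 0.394,
                                   comp = tissue_composition("squamous_cell_carcinoma")) {
  mode <- match.arg(mode)
  if (any(f18O < 0 | f18O > 1)) stop("f18O must lie in [0, 1]")
  if (mode == "mc_constant") return((1 - f18O) * constant)
  iso <- isotopes()
  nd <- atoms_per_gram(comp)
  (nd[["N_O"]] * (1 - f18O) * iso["N13", "integrated_xs_mb_MeV"]) /
    (nd[["N_N"]] * iso["C11", "integrated_xs_mb_MeV"])
}

#' Infer the 18O enrichment from the 18F/11C activity ratio
#'
#' Inverts the yield-expression ratio:
#' \deqn{f_{18O} = \frac{A_{18F}}{A_{11C}}\cdot\frac{N_N}{N_O}\cdot
#'       \frac{\int\sigma_{11C}}{\int\sigma_{18F}}.}
#' Both activities must be decay-corrected to a common reference time.
#' Relative uncertainties are propagated in quadrature; results outside
#' `[0, 1]` are clipped and flagged.
#'
#' @param A_18F,A_11C decay-corrected activities in the same (arbitrary)
#'   units, both > 0 (A_18F = 0 is allowed and yields f = 0).
#' @param comp a [tissue_composition()].
#' @param rel_unc named relative 1-sigma uncertainties of the two activities
#'   (e.g. `c(A_18F = 0.05, A_11C = 0.05)`), optional.
#' @param convention see [relative_yields()]; must match the convention the
#'   supplied amplitude ratio is interpreted in.
#' @return A list with `f18O`, `se`, `clipped`, and `f18O_percent`.
#' @export
infer_f18O <- function(A_18F, A_11C, comp, rel_unc = c(A_18F = 0, A_11C = 0),
                       convention = c("production", "activity")) {
  convention <- match.arg(convention)
  stopifnot(inherits(comp, "tissue_composition"))
  if (A_11C <= 0) stop("A_11C must be > 0")
  if (A_18F < 0) stop("A_18F must be >= 0")
  iso <- isotopes()
  nd <- atoms_per_gram(comp)
  lam_fac <- if (convention == "activity")
    iso["C11", "lambda_per_min"] / iso["F18", "lambda_per_min"] else 1
  f <- (A_18F / A_11C) * (nd[["N_N"]] / nd[["N_O"]]) *
    (iso["C11", "integrated_xs_mb_MeV"] / iso["F18", "integrated_xs_mb_MeV"]) *
    lam_fac
  rel <- sqrt(sum(rel_unc^2))
  clipped <- f < 0 || f > 1
  fc <- min(max(f, 0), 1)
  list(f18O = fc, se = fc * rel, clipped = clipped, f18O_percent = 100 * fc)
}

#' Order-of-magnitude Bragg-peak activity estimator
#'
#' Estimates the \eqn{^{18}}F activity concentration produced by delivering a
#' given dose near the Bragg peak to a water-like target partially loaded
#' with \eqn{^{18}}O-enriched water.  The documented approximation chain is:
#' fluence from the surface dose via the stopping power at the beam energy;
#' peak production density \eqn{\Phi\, n_{18O}\, \sigma_{eff}} with an
#' effective cross section \eqn{\sigma_{eff} = 2\int\sigma\,dE/(E_p -
#' E_{thr})} (triangular spectral model of the excitation function); and
#' activity \eqn{\lambda_{18F} N}.  The result is an order-of-magnitude
#' estimate only: it ignores transport, straggling and the detailed shape of
#' the excitation function.
#'
#' @param dose_gy delivered dose in Gy (> 0; 0 returns 0).
#' @param enrichment fraction of the target water replaced by enriched water,
#'   in `[0, 1]`.
#' @param purity isotopic purity of the enriched water (fraction of its O
#'   that is \eqn{^{18}}O).
#' @param comp target composition (default water).
#' @param table stopping-power table (default bundled water).
#' @param Ep beam energy, MeV.
#' @return Activity concentration in Bq/mm^3 (order of magnitude).
#' @export
predict_bp_activity <- function(dose_gy, enrichment, purity = 1,
                                comp = tissue_composition("water"),
                                table = sp_material("water"), Ep = 7.5) {
  if (dose_gy < 0) stop("dose must be >= 0")
  if (enrichment < 0 || enrichment > 1) stop("enrichment must lie in [0, 1]")
  if (dose_gy == 0) return(0)
  iso <- isotopes("F18")
  S <- interpolate_sp(table, Ep)                   # MeV cm^2/g
  phi <- dose_gy / (S * .const$mev_to_gy)          # protons/cm^2
  n18 <- enrichment * purity * atoms_per_gram(comp)[["N_O"]] * table$density  # per cm^3
  sigma_eff <- 2 * iso$integrated_xs_mb_MeV / (Ep - iso$threshold_MeV) * 1e-27  # cm^2
  n_f18 <- phi * n18 * sigma_eff                   # nuclei per cm^3
  lambda_s <- iso$lambda_per_min / 60
  lambda_s * n_f18 / 1e3                           # Bq/mm^3
}
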