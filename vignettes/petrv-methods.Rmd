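---
title: "Models and methods in petrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in petrv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrv)
```

`petrv` models an experiment in which a tumour loaded with ¹⁸O-enriched
water is irradiated with ~8-MeV protons — the energy protons have in the
last millimetre of a clinical beam — and the resulting positron-emitter
activity is used to verify where the beam stopped. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Beam physics

**Stopping power and range.** Proton transport is described entirely by the
mass stopping power $S(E)$ of each traversed material. The bundled tables
for water, air and kapton are *synthetic reference tables*: the canonical
ICRU-49/PSTAR tabulations are not redistributable here, so
`tools/make_sp_tables.R` computes them from Bethe stopping-power theory with
the ICRU-49 mean excitation energies (water 75 eV, air 85.7 eV, kapton
79.6 eV) plus a smooth shell-correction term calibrated to published PSTAR
anchor values for water. The acceptance suite verifies that the integrated
ranges land on published values (0.74 mm at 7.50 MeV, 115 µm at 2.6 MeV in
water) to better than the 3% check tolerance, and that the kapton-window +
7.5-cm-air beamline degrades 8.00 MeV protons by 0.50 MeV.

Numerical choices, all exercised by tests:

* interpolation is log–log linear and *refuses* queries outside the grid;
* the CSDA integral $R(E)=\int_0^E dE'/(\rho S(E'))$ uses an adaptive
  trapezoid rule on a log-spaced subgrid with relative tolerance $10^{-4}$;
* the below-grid tail (the last ~2 µm) assumes $S\propto E^{-0.8}$, a
  power-law extrapolation whose error is negligible against the 3% range
  checks;
* layer degradation integrates $dE/dx=-\rho S(E)$ with fourth-order
  Runge–Kutta (400 steps per layer) and raises a "stopped in layer *k*"
  error, with the residual range, when a layer exceeds the residual range.

**Spot model and maps.** The beam spot is a single 2-D Gaussian whose
spreads $\sigma_x(z),\sigma_y(z)$ vary with distance as a second-degree
polynomial fitted per axis (`fit_sigma_polynomial()`); spot images are
fitted either by image moments or by Levenberg–Marquardt least squares
initialised from the moments (the default, more robust to noise; both
choices are exposed). Plan fluence is the analytic sum of normalised
Gaussians, evaluated either pointwise or on a regular cell-centre grid
(default pitch 0.05 mm, extent ±5 mm in beam's-eye view, origin at the plan
centroid). Protons per spot are $N = I t/e$, ignoring current ripple. The
grid must cover 4σ beyond the outermost spot, which bounds the discarded
tails: the grid integral matches the delivered protons to 0.1%. Surface
dose is $D=\Phi\,\bar S\,(1.602\times10^{-10})$ Gy with $\bar S$ the mean
stopping power over a thin slab (default 100 µm) obtained by slowing the
proton across it; no Bragg-curve reconstruction is attempted because every
dose quantity the package reports is a surface quantity.

**Dose homogeneity.** There is no canonical homogeneity index for a 3×3
spot grid, and plausible metrics (max deviation from centre, range ratio,
CV) differ by factors. `dose_homogeneity()` therefore exposes the metric
and radius as parameters rather than hard-coding any single figure.

## Activation model

Per-isotope production in ¹⁸O-enriched tissue is
$$A_{18F}=A_0N_Of_{18O}\textstyle\int_0^{E_p}\sigma\,dE,\qquad
  A_{13N}=A_0N_O(1-f_{18O})\textstyle\int\sigma\,dE,\qquad
  A_{11C}=A_0N_N\textstyle\int\sigma\,dE,$$
with $N_O,N_N$ the oxygen/nitrogen atoms per gram (nominal masses 16 and
14; the composition presets are quoted to three digits so isotopic mass
refinements are irrelevant), and the packaged cross-section integrals valid
only at $E_p=7.5$ MeV — other energies require user-supplied integrals,
and energies at or above 16.79 MeV are refused outright because they open
the ¹⁵O channel that the three-isotope model excludes.

Two deliberate subtleties:

* **Nuclei versus activity.** As written the expressions are proportional
  to *produced nuclei*; they contain no decay constant. Whether the
  corresponding measured quantities are nuclei-proportional or
  activity-proportional (an extra $\lambda_i$) is ambiguous, so
  `relative_yields()` and `infer_f18O()` take a `convention` switch
  (`"production"`, the default and the convention used throughout the
  pipeline, or `"activity"`). Choosing `"activity"` rescales an inferred
  enrichment by $\lambda_{11C}/\lambda_{18F}\approx5.4$ — a systematic
  well worth being explicit about.
* **The 0.394 constant.** The expected ratio $A_{13N}/A_{11C}$ used as the
  a-priori fit constraint is $(1-f)\cdot0.394$, a constant calibrated by a
  full Monte Carlo transport simulation. The transparent ratio computed
  from the packaged integrals and the tissue composition is $\approx
  8.4\,(1-f)$ — more than an order of magnitude larger, because the
  calibrated constant absorbs the fluence/stopping-power weighting of the
  transport calculation (and possibly a decay-constant convention). The
  package treats 0.394 as an opaque calibrated constant (the default for
  fitting, `mc_constant`), keeps the transparent `xs_integral` mode
  available, and makes no attempt to reconcile the two.

`predict_bp_activity()` is an *order-of-magnitude* feasibility estimator:
fluence from dose via the stopping power at the beam energy, peak
production density $\Phi\,n_{18O}\,\sigma_\mathrm{eff}$ with
$\sigma_\mathrm{eff}=2\int\sigma\,dE/(E_p-E_\mathrm{thr})$ (a triangular
model of the excitation function), activity via $\lambda_{18F}$. For the
2-Gy / 30%-enrichment scenario it yields ≈0.1 Bq/mm³, a factor ≈5 below
the published full-transport estimate of 0.5 Bq/mm³; every transparent
variant we examined (flat excitation function, dose evaluated deeper in
the peak) moves the estimate *down*, so the gap appears to originate in
the transport weighting and cross-section data of the reference
simulation, not in an algebra slip. The estimator is labelled and tested
as order-of-magnitude only.

## Decay-curve decomposition

Events are filtered to the 511-keV photopeak window. The phrase "±10%
energy window" is read as a fractional *half*-width (459.9–562.1 keV); the
alternative total-width reading is selectable. Counts are histogrammed in
10-s bins (configurable) on the package-wide time origin — **the end of
irradiation** — and the measured background rate times the bin width is
subtracted. Irradiations are ~90 s, so origin conventions that differ by
the irradiation itself are sub-percent on every decay correction; the
origin is nonetheless explicit everywhere. Bins overlapping declared
live-time gaps (one scenario has a 10-min counter stop) are masked out of
all fits.

The decay model is one exponential per isotope with decay constants fixed
at the physical values, fitted to *bin-integrated* expected counts (not
midpoint rates) by weighted least squares with Neyman weights
$\mathrm{var}_k=\max(\mathrm{raw}_k,1)+\sigma^2_{bkg,k}$. With fixed
$\lambda_i$ the model is linear in the amplitudes, so the non-negative
least-squares problem is solved *exactly* by active-set enumeration (at
most three free parameters) rather than by an iterative optimiser;
amplitudes pinned at the zero bound are flagged, covariance is
$(X^TWX)^{-1}$ on the free set, and noiseless model data are recovered to
machine precision. The fit quotes amplitudes in counts/s at the end of
irradiation, a $\chi^2$ and its degrees of freedom.

**The constraint and the enrichment fixed point.** Because the ¹¹C and ¹³N
half-lives are commensurable, a 29-min window cannot separate them well;
the a-priori tie $A_{13N}=A_{11C}(1-f)\cdot0.394$ removes the degeneracy.
The enrichment $f$ itself comes from the fitted $A_{18F}/A_{11C}$ ratio,
and the unconstrained ¹¹C amplitude is noisy enough (≈50% relative at the
packaged scenario scale) that a plain ratio estimate is strongly
skew-biased. The pipeline therefore iterates the weak dependence:
constrained fit at $f=0$, infer $f$, refit with the inferred value (both
measurement windows share this constraint value, so identical inputs give
exactly unit retention), and infer once more. The $(1-f)$ factor changes
by <3% over the whole enrichment range, so one iteration suffices;
replicate studies in the test suite show the resulting estimator recovers
a 3.0% enrichment with negligible bias.

**Retention.** Washing retention is the ratio of post- to pre-wash
amplitudes at the common reference time (the physical decay factor cancels,
so the ratio is independent of the reference choice), with first-order
error propagation. ¹¹C and ¹³N are additionally pooled under the
assumption that their ratio survives washing — by the time the post-wash
measurement starts, more than five ¹³N half-lives have elapsed, so the
pooled number is dominated by ¹¹C and carries a large uncertainty; the
non-negativity bound also gives the pooled ratio a small upward truncation
bias at low true retention, visible in the replicate studies.

## Washout model

Dynamic PET decay curves are fitted to physical × biological decay,
$A(t)=A_0e^{-(\lambda_{phys}+\lambda_{bio})t}$ with
$\lambda_{phys}$ fixed at ¹⁸F and $\lambda_{bio}\ge0$ free
(bounded Levenberg–Marquardt). The model is integrated over each 60-min
frame by default; midpoint evaluation is a documented option that differs
by well under 1% at these frame lengths. Derived half-lives obey
$1/T_{comb}=1/T_{phys}+1/T_{bio}$ *by construction*; confidence intervals
come from first-order propagation of the fitted $\lambda_{bio}$ standard
error with a $t$ quantile on the residual degrees of freedom, transformed
through the monotone half-life map (bootstrap is unnecessary at the tested
noise levels: empirical 95% CI coverage over 500 seeded replicates sits at
≈96–97%). A fitted $\lambda_{bio}$ below $10^{-8}$ min⁻¹ (a biological
half-life beyond a century) is reported as "no detectable washout".

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of `(scenario, seed)`. Event streams draw
per-isotope inhomogeneous-Poisson times by inverse-CDF sampling of the
exponential intensity, photopeak energies as a Gaussian at 511 keV with
the detector's 6%-at-662-keV resolution scaled as $1/\sqrt E$, and a flat
300–700 keV background whose in-window rate equals the scenario's stated
background (default 1 count/s; the real detector is low-activity but its
rate is not published, so this is a calibration choice). Dynamic-PET TACs
are frame-integrated model values with Gaussian noise at a stated CV
(default 3%).

The packaged scenarios encode the modelled measurement conditions: 29-min
pre-wash windows starting 10 min after irradiation, 22-min post-wash
windows starting at 50 min, enrichment 0.61%–3.0%, retention truth 0.59
(¹⁸F) / 0.14 (others), one scenario with a 10-min acquisition gap, and
nine 60-min PET frames starting 3.5–4 h after irradiation with biological
half-lives of 14.7 h and 21 h. Absolute count-rate scales are *not*
published, so the presets use a calibrated scale (¹¹C at 40 counts/s,
hence a ¹⁸F-dominated total of a few hundred counts/s pre-wash) chosen so
that the pooled ¹¹C/¹³N retention uncertainty reproduces the ±26-point
precision pattern of the modelled experiment. Pure counting statistics at
this scale make the ¹⁸F retention *more* precise (≈±1 point) than the
±9 points of the real experiment — the real error budget evidently
includes systematic components (positioning, efficiency) that the
generator deliberately does not model. Passing recovery tests therefore
demonstrate statistical self-consistency of the estimators, not immunity
to systematics. Also not modelled: Compton continua and scatter, detector
dead time, PET image reconstruction, and any tumour biology.

## Problem sizes and reproducibility

The replicate studies in the tests and the acceptance script use 500
seeded Poisson replicates for amplitude/retention coverage, 500 replicates
for washout CI coverage, 200 replicates for the end-to-end
enrichment/retention averages, and 100–1000-draw Monte Carlo oracles for
uncertainty propagation — sizes at which binomial fluctuation bands
(e.g. coverage within [60%, 76%] at nominal 68%) are comfortably
discriminating. Every stochastic routine takes an explicit seed, and the
acceptance script derives all of its seeds from a single `--seed`
argument.

## Known limitations

* The stopping-power fixtures are theory-derived surrogates validated
  against published anchors, not the reference tabulations themselves.
* The 0.394 constraint constant is opaque; analyses at other beam energies
  or compositions would need a new transport calibration.
* Retention estimators inherit truncation bias near the zero bound; the
  pooled ¹¹C/¹³N figure is only meaningful together with its uncertainty.
* The Bragg-peak activity estimator is order-of-magnitude by design.
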