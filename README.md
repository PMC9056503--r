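# petrv — proton-activation PET range verification analysis

`petrv` implements the computational chain behind PET-based range
verification of low-energy proton beams in targets loaded with
¹⁸O-enriched water ("18-W"). When tissue water is partially replaced by
18-W, protons in the last millimetre of their path activate ¹⁸O through the
low-threshold ¹⁸O(p,n)¹⁸F reaction; the resulting ¹⁸F⁻ ions stay trapped in
cells, so a PET signal marks where the beam stopped — even hours later.
The package is aimed at medical-physics researchers who want to plan such
irradiations, decompose the resulting counting data into isotope
contributions, and quantify enrichment, retention and biological washout.

It provides, in one coherent toolchain:

* **Analytic beam physics** — proton stopping-power tables with log-log
  interpolation, CSDA ranges `R(E) = ∫ dE′/(ρS(E′))`, layer-by-layer energy
  degradation, Gaussian beam-spot calibration (`σ(z)` polynomials, 2-D spot
  fits), and spot-plan fluence / surface-dose maps
  `Φ(x,y) = Σ N/(2πσxσy)·exp(−Δx²/2σx² − Δy²/2σy²)`.
* **Activation yields** — per-isotope production in ¹⁸O-enriched tissue,
  `A(¹⁸F) ∝ N_O·f(¹⁸O)·∫σ(¹⁸O(p,n))dE`, etc., with inference of the
  enrichment fraction f(¹⁸O) from the ¹⁸F/¹¹C amplitude ratio.
* **Decay-curve decomposition** — 511-keV windowing, background
  subtraction, and the constrained triple-exponential fit
  `A(t) = A₁₈F·e^(−λ₁₈F t) + A₁₁C·e^(−λ₁₁C t) + A₁₃N·e^(−λ₁₃N t)`
  with fixed decay constants, non-negative amplitudes and the a-priori tie
  `A₁₃N/A₁₁C = (1−f)·0.394`, plus decay correction and washing-retention
  estimation.
* **Biological washout** — fits of dynamic PET time-activity curves to
  physical × biological decay, `A(t) = A₀·e^(−(λ_phys+λ_bio)t)`, with the
  half-life algebra `1/T_comb = 1/T_phys + 1/T_bio`.
* **Seeded synthetic data** — list-mode gamma-event streams (inhomogeneous
  Poisson + Gaussian photopeak + flat background), binned count series,
  dynamic-PET TACs and film-like spot images, all pure functions of
  `(scenario, seed)` with embedded ground truth.

## Worked example

Plan the nine-spot irradiation and check the delivered fluence and dose:

```r
library(petrv)
plan <- grid_plan_3x3()                  # 3x3 grid, 1.2 mm pitch, 6 nA x 10 s
fluence_at(plan, 0, 0, sigma_x = 0.78, sigma_y = 0.89)
#> [1] 2.50006e+13        # protons/cm^2 at the plan centre
surface_dose(2.5e13, E = 7.5, slab_um = 100)
#> [1] 237676.9            # Gy averaged over the first 100 um of water
```

Simulate a high-enrichment ex-vivo counting experiment and run the full
inverse analysis (window → bin → subtract → constrained fits → enrichment →
retention):

```r
spec <- paper_scenario("T4")             # f(18O) truth 3.0%, retention 0.59 / 0.14
pre  <- simulate_event_stream(spec, "pre",  seed = 7)
post <- simulate_event_stream(spec, "post", seed = 8)
res  <- exvivo_analysis(pre, post, background_rate = spec$background_rate)
res$pre
#> <decay_fit> amplitudes at end of irradiation [counts/s]:
#>   F18:   215.211 +- 1.529
#>   C11:    39.638 +- 2.388
#>   N13:    15.137 +- 0.912
#>   constraint: ratio (f18O = 0.03073, constant 0.394);  chi-square 184.9 on 172 dof
res$f18O$f18O_percent                    # inferred enrichment, truth 3.0
#> [1] 3.043445
res$retention
#> Retention fractions (post-wash / pre-wash, decay-corrected):
#>   F18              58.7% +- 1.1%
#>   C11              10.9% +- 26.2%
#>   N13              10.9% +- 26.2%
#>   C11_N13_pooled   10.9% +- 26.2%
```

The fitted ¹⁸F amplitude dominates, the inferred enrichment recovers the
3% ground truth, and washing retains ~59% of the ¹⁸F signal while the
short-lived isotopes are mostly gone — the large pooled uncertainty
reflects how little ¹¹C/¹³N activity survives to the post-wash window.

Fit the washout model to a noiseless nine-frame dynamic PET curve:

```r
fit_washout(simulate_tac(paper_scenario("E1"), noise = FALSE))
#> <washout_fit> F18 physical decay x biological washout (9 frames)
#>   T_comb = 97.62 min  [97.62, 97.62] 95% CI
#>   T_bio  = 14.7 h    [14.7, 14.7] 95% CI
```

A 14.7-h biological half-life shortens the observed ¹⁸F half-life from
109.77 to 97.6 min and still leaves `biological_retention(8, 14.7)` ≈ 69%
of the activity in place 8 h after irradiation.

A thin command-line workbench wraps the same functions
(`inst/exec/petrv plan|simulate|fit-decay|fit-washout|exvivo|invivo`,
YAML configs as in `inst/extdata/example_config.yaml`, JSON reports).

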