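# polyion

Analysis of hydrophobic weak-base polyelectrolyte solutions — linear
polyethylenimine (PEI) being the motivating case — for polymer physicists and
gene-delivery researchers who need to track, from routine bench measurements,
(i) how much of the polymer is protonated at a given pH, and (ii) how the
polymer partitions between free chains and aggregates.

The package covers three measurement types and a forward simulator:

* **Dynamic light scattering (DLS).** The intensity autocorrelation of a PEI
  solution typically shows two relaxations, one from free chains and one from
  aggregates. `fit_correlation()` decomposes G(t) − 1 into stretched
  exponentials (Kohlrausch–Williams–Watts modes),

  G(t) − 1 = Σᵢ Aᵢ exp(−(t/τᵢ)^γᵢ),

  selects one vs two modes by a corrected-AIC rule (`select_mode_count()`),
  and sizes each mode through the diffusive relation τ⁻¹ = D q² with
  q = (4πn/λ) sin(θ/2) and the Stokes–Einstein equation
  R_h = k_B T / (6πηD) (`size_modes()`). `intensity_fractions()` gives the
  free/aggregate split from the amplitudes; `diffusive_scaling_check()`
  verifies the linear τ⁻¹ vs q² dependence across scattering angles.

* **Constant-concentration pH titration.** With separate samples receiving
  log-spaced acid/base doses (so polymer and salt concentrations never
  change), electroneutrality gives the protonated amine concentration
  directly from the measured pH:

  [AH⁺] = [OH⁻] + [Cl⁻]_HCl − [H⁺] − [Na⁺]_NaOH,  P = [AH⁺]/[A]₀.

  `analyze_titration()` applies this with dose-matched polymer-free control
  correction; `buffering_capacity()` (β = |d dose/d pH|), `apparent_pkas()`
  and `detect_stalls()` extract the buffering maxima and the stalled charge
  states; `ninhydrin_signal()` predicts the colorimetric signal of the
  unprotonated amines.

* **Vapor-pressure osmometry.** `virial_fit()` fits
  Π V₁/(RT) = c/M + B₂c² + B₃c³ on the molecularly dispersed branch and
  `association_profile()` flags the plateau or maximum that marks an
  associating solution.

* **Forward simulation.** `protonation_isotherm()` defines a ground-truth
  charge-vs-pH curve as logistic steps between stalled levels (defaults: 0,
  44, 70, 95 % charge with transitions at pH 10, 4.5 and 2.75);
  `simulate_titration()` solves the electroneutrality equation for pH at
  every dose (residual < 1e−12 mol/L), and `simulate_correlation()` /
  `simulate_osmometry()` generate the other two measurement types. Every
  analysis stage is validated by recovering the generator's parameters.

## Worked example

Decompose a simulated two-population DLS curve (free chains 5 nm, aggregates
140 nm, 10 mM NaCl, 633 nm / 173°, 1 % noise):

```r
library(polyion)
geom  <- dls_geometry(633, 173)
solv  <- solvent_spec(298.15, nacl_M = 0.01)
pop   <- population_spec(free_radius_nm = 5, aggregate_radius_nm = 140,
                         free_intensity_fraction = 0.35)
curve <- simulate_correlation(pop, geom, solv, noise_sd = 0.01, seed = 7)
summary(fit_correlation(curve, n_modes = "auto"))
#> KWW fit: 2 mode(s), residual norm 0.0816
#>   amplitude relaxation_time_s   stretch population diffusion_coefficient_m2s
#> 1 0.3608156      2.980982e-05 0.7906728       free              4.829995e-11
#> 2 0.6427101      8.381688e-04 0.8085282  aggregate              1.717808e-12
#>   hydrodynamic_radius_nm
#> 1               5.070525
#> 2             142.568989
#> Intensity fractions: free 0.360, aggregate 0.640
```

The auto rule finds two relaxations; the fitted radii (5.07 and 142.6 nm)
recover the simulated 5 and 140 nm populations, and the amplitude split
(0.36/0.64) matches the generated intensity fractions. The stretch exponents
(~0.79–0.81) fall in the 0.7–0.85 band expected for mildly polydisperse PEI.

Titrate 4.08 mM amine in 150 mM NaCl and read off the charge states:

```r
iso  <- protonation_isotherm()           # stalled levels 0/0.44/0.70/0.95
sim  <- simulate_titration(iso, titration_design(), ph_noise_sd = 0)
summary(analyze_titration(sim))
#> Protonation curve: 5765 samples, pH 2.95-11.60, [A]0 = 0.00408 M, P range 0.000-0.705
#> Apparent pKa: 4.50, 10.01
#> Stalled charge states:
#>   fraction_level   ph_min   ph_max
#> 1      0.7000755 3.033089 4.092411
#> 2      0.4391799 4.917934 9.165553
```

The charge-balance analysis recovers the generating isotherm: a 44 % stall
across the neutral region, a 70 % stall between pH ~3 and ~4.1, and the two
apparent pKa at 4.5 (free-polymer transition) and ~10 (basic transition).

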