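---
title: "Models and methods behind polyion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyion)
```

polyion analyzes the solution behaviour of hydrophobic weak-base
polyelectrolytes such as linear polyethylenimine (PEI). This vignette is the
package's own account of the models it implements, the defaults it chooses
where the underlying science leaves them open, and what its synthetic-data
validation does and does not demonstrate.

## 1. DLS decomposition

### Model

The intensity autocorrelation of a polyelectrolyte solution containing both
free chains and aggregates is modelled as a sum of one or two stretched
exponentials,

$$G(t) - 1 = \sum_i A_i \exp\!\big(-(t/\tau_i)^{\gamma_i}\big),$$

where $A_i$ is the intensity contribution, $\tau_i$ the relaxation time and
$\gamma_i \le 1$ the stretch (polydispersity) exponent of mode $i$. A
diffusive mode satisfies $\tau^{-1} = D q^2$ with
$q = (4\pi n/\lambda)\sin(\theta/2)$, and the hydrodynamic radius follows
from Stokes–Einstein, $R_h = k_B T / (6\pi\eta D)$. For mildly polydisperse
PEI ($M_w/M_n \approx 1.2$) the stretch exponents fall around 0.7–0.85;
fitted values outside that band are reported with a warning rather than
rejected, since they are legitimate solutions of the least-squares problem.

### Numerical strategy

Sums of stretched exponentials are ill-conditioned and the loss surface is
multi-modal, so `fit_correlation()`:

1. scores a coarse grid of $(\tau, \gamma)$ combinations (32 log-spaced
   $\tau$ across the lag window, $\gamma \in \{0.6, 0.7, 0.8, 0.9, 1\}$),
   solving amplitudes in closed form from one precomputed Gram matrix;
2. refines the best few distinct seeds with bounded Levenberg–Marquardt
   (`minpack.lm`), keeping the lowest residual;
3. re-sorts modes by relaxation time on output (modes may cross during
   optimization; the final order defines the free/aggregate labels).

Bounds: $A \ge 0$, $\gamma \in (0.5, 1]$, $\tau$ within the observed lag
window times $[0.01, 100]$. The $\gamma$ bound is deliberately wider than
the observed 0.7–0.85 band to avoid biasing recovery. Residuals are
unweighted, as no noise model is available for the instrument readout; the
amplitudes are fitted unnormalized, so the reported intensity *fractions*
are invariant to any overall scaling of $G(t)-1$.

### Mode count and lone-mode classification

Whether a curve shows one or two relaxations is usually judged by eye. The
package replaces that judgement with a reproducible rule: two modes are
accepted only if they improve the corrected Akaike criterion by at least 10
*and* each amplitude carries at least 2 % of the total. A lone mode is
classified by size: below 20 nm it is a free chain (a 2.5 kDa chain of
contour length ~19 nm cannot exceed that), otherwise an aggregate
(aggregates are ≥ 100 nm).

### Solvent viscosity

Pure-water viscosity uses the Vogel-type correlation
$\eta(T) = 2.414\times10^{-5}\,10^{247.8/(T-140)}$ Pa s (better than 1 %
over 0–100 °C), corrected for NaCl with a Jones–Dole term
$\eta/\eta_w = 1 + A\sqrt{c} + Bc$ ($A = 0.0062$, $B = 0.0793$ L/mol at
25 °C), which is monotone increasing over the sub-molar range used here.
Defaults are 25 °C and refractive index 1.33, both overridable.

## 2. Charge-balance titration analysis

Dissolving a weak-base polymer with HCl/NaOH and NaCl, electroneutrality
requires

$$[\mathrm{AH^+}] + [\mathrm{H^+}] + [\mathrm{Na^+}] =
  [\mathrm{OH^-}] + [\mathrm{Cl^-}],$$

and after the added NaCl cancels,

$$[\mathrm{AH^+}] = [\mathrm{OH^-}] + [\mathrm{Cl^-}]_{HCl}
  - [\mathrm{H^+}] - [\mathrm{Na^+}]_{NaOH}, \qquad
  P = [\mathrm{AH^+}]/[\mathrm{A}]_0.$$

pH is treated as $-\log_{10}$ of concentration (ideal solution) and
$k_w = 10^{-14}$ is held fixed; the underlying equations are written in
concentrations, and ionic-strength activity corrections are out of scope.
Three conventions deserve note:

* **Control correction.** Polymer-free controls receiving the same doses
  track spurious H⁺ uptake (dissolved CO₂). The control's *apparent*
  [AH⁺], computed with the same charge balance, is subtracted dose by dose
  (matched exactly on the signed dose).
* **Dissolution baseline.** Acid added to dissolve the stock polymer is not
  part of the titration dose axis; it can be supplied as a constant
  `baseline_offset_M` (default 0).
* **Out-of-range P.** In the basic region the inferred charge can go
  negative. This is a bookkeeping consequence of the hydroxide accounting,
  not a physical charge state; values are reported unclamped with a flag.

Buffering capacity is $\beta(\mathrm{pH}) = |d(\text{dose})/d\,\mathrm{pH}|$
by centered finite differences on dose-sorted samples; apparent pKa are the
largest local maxima of $\beta$ after a 5-point moving-average smoothing
(ties broken toward lower pH). Stalled charge states are contiguous windows
of at least 1 pH unit with $|dP/d\mathrm{pH}| < 0.02$, matching the width of
the plateaus the method is meant to detect. Because $\beta$ is a finite
difference, it is only trustworthy where the dose grid resolves the pH axis;
the test suite uses denser grids (up to 1000 doses per decade) when checking
$\beta$ against the closed-form ideal-buffer expression near the steep
equivalence-point jump.

## 3. Osmotic virial analysis

For molecularly dispersed solutions the reduced osmotic pressure follows
$\Pi V_1/(RT) = c/M + B_2 c^2 + B_3 c^3$. `virial_fit()` performs the
zero-intercept polynomial fit (concentrations converted from amine molarity
to mass via the 43.07 g/mol repeat unit, so $M$ is in g/mol). Association
makes the signal plateau or peak; the expansion then no longer applies, so
the default fit range stops below the detected plateau onset, and an
explicitly requested range that crosses a plateau is refused. Plateau
detection uses finite-difference slopes normalized to the initial slope
(threshold 0.1, two consecutive intervals); vapor-pressure readouts without
absolute calibration yield apparent (scaled) parameters with a flag, since
$1/M$ scales with the signal while the association signatures do not.

## 4. The synthetic generator and its defaults

The generator exists so that every analysis can be validated by parameter
recovery without instrument data. Its defaults *are* the study conditions.

**Isotherm.** The ground-truth charge curve is a sum of base-10 logistic
steps between stalled levels — the natural generalization of
Henderson–Hasselbalch, which is the single step with decade-width 1.
Defaults: levels $\{0, 0.44, 0.70, 0.95\}$, centers $\{10, 4.5, 2.75\}$,
decade widths $\{0.4, 0.18, 0.12\}$. These encode the reported behaviour of
2.5 kDa linear PEI: a 44 % plateau across the neutral region persisting to
pH ~9, the acidic stall near 70 % spanning at least one pH unit (~3–4.1),
and a final rapid rise below pH 3 that is essentially complete (~95 %) by
pH 2.5 — hence a midpoint of 2.75 rather than 2.5, and widths narrow enough
that the stalls exist under the package's own plateau criterion. A uniform
width (e.g. 0.6 decades for all transitions) would contradict that
narrative: the neutral plateau would sag several points below 44 % and the
70 % stall would never satisfy the slope/span rule.

**Titration design.** Doses are log-spaced on each side (HCl positive,
NaOH negative), default 1 µM to 4 mM at 800 per decade. The density is
deliberately high: on the neutral plateau the polymer barely buffers, so
the entire pH 7–9 window corresponds to a ~2 % change in dose, and a
realistic few-dozen-sample design would leave that window empty. The
acid-side default stops near pH 3; reaching the low-pH endpoint (~pH 2.4)
is done by extending `acid_max_M` to 8 mM, which also brings the third
(low-pH) buffering peak into view. Solving for pH uses vectorized bisection
on (0.5, 13.5) followed by Newton polishing, leaving electroneutrality
residuals at machine precision (far below the 1e−12 mol/L requirement);
pH read noise (default 0.02 units, additive Gaussian) is optional and
seeded.

**DLS and osmometry.** Radii are converted to relaxation times through the
same Stokes–Einstein path used in analysis; noise is multiplicative
Gaussian on $G(t)-1$ (1 % default, matching a well-averaged correlator) on
a 200-point log grid over $10^{-7}$–$1$ s. Osmotic curves follow the virial
form below the association onset and blend logistically into a plateau
above it; noise is relative Gaussian.

**What recovery does and does not show.** Passing recovery tests shows the
analysis inverts its own forward model correctly at realistic noise levels —
it does not validate the forward models against real instruments. Real DLS
baselines drift and correlate across lags; real titrations have activity
effects, CO₂ ingress and electrode drift beyond the idealized control
correction; real osmometers need calibration. The generator also keeps
$P \in [0,1]$, so the negative apparent charges seen in basic-region
analyses of real data appear here only if the analysis is run with
deliberately mismatched accounting.

## 5. Known limitations

* At most two KWW modes; no CONTIN-style regularized inversion.
* Ideal-solution pH throughout; no activity or temperature dependence of
  $k_w$.
* Two-mode fits at 1 % noise have a radius uncertainty of a few percent
  (the $\tau$–$\gamma$ correlation is strong); parameter-recovery checks at
  fixed noise therefore pin the random seed.
* The association plateau is detected, not modelled: no mechanism or
  salt-dependence of $B_2$ is implied.

## 6. Problem sizes

The default validation pipeline (`reproduce_analysis()`) uses ~5 800
titration samples plus controls, 200-point correlation curves and 12–16
point osmotic series; it completes in about a second on one CPU, and the
full test suite in a few seconds.
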