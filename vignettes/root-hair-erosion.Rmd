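---
title: "Methods: root-soil cohesion and erosion-reduction modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root-soil cohesion and erosion-reduction modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizocohere)
```

This vignette documents the models behind `rhizocohere`, the assumptions
they make, the tunable parameters, the numerical choices, and the known
limitations. The package analyses four coupled experiments on root-soil
cohesion — a centrifuge gel-adhesion assay, uprooting pull tests, flume
erosion runs, and a mechanistic erosion model — and ships generators that
emulate each data stream so the pipeline is testable end to end.

## Centrifuge detachment mechanics

Seedlings grown on the surface of a gel plate are spun in a swing-out
centrifuge. At speed setting $n$ the rotor turns at $720\sqrt{n}$ rpm.
Balancing moments about the bucket hinge shows the bucket's deviation
from the plane of rotation is bounded by
$\theta < \arctan\!\big(g/(0.07\,\omega^2)\big)$, under $1.5^\circ$ even
at the slowest setting (`bucket_inclination()`), so the plate is treated
as exactly perpendicular to the rotor and the only force on a seedling is
the centrifugal pull $F_c = M_s\,\mathrm{radius}\,\omega^2$ on its aerial
mass $M_s$. Because $\omega^2 \propto n$, force grows linearly in the
setting index and linearly in mass; both scalings are asserted exactly in
the tests.

`detachment_curve()` places each seedling on a *force* axis (not a
setting axis): masses differ, so two seedlings detaching at the same
setting experienced different forces. Seedlings still attached after the
maximum tested setting are censored at that setting's force and never
counted as events; the curve itself is the Kaplan-Meier product-limit
estimate (computed with `survival::survfit`), a right-continuous,
non-increasing step function starting at 1. Tied detachment forces drop
the curve once. Proportional-hazards regression on the exported event
table is deliberately out of scope — `export_event_table()` produces the
analysis-ready input (force, event flag, genotype, covariates) for
`survival::coxph`.

Gravity defaults to $9.81\ \mathrm{m\,s^{-2}}$ and is configurable; the
residual sub-$1.5^\circ$ tilt is ignored in the force calculation, the
same idealisation the moment-balance bound justifies.

## Uprooting trace analysis

A pull test records load $f$ (N) against displacement $x$ (m). The
root-soil system deforms quasi-elastically, $f(x) = k(x)\,x$, up to the
peak at $x_p$; beyond it damage accumulates and the load declines to zero
at the uprooting displacement $x_u$. The package does not estimate the
latent moduli $k$ and $h$ — peak force, total energy and force-drop
magnitudes are the macroscopic summaries on which genotypes are compared.

Numerical choices:

* **Noise threshold.** Loads below 0.05 N (the accuracy floor of a 10 N
  load cell) are ignored when locating the peak; 0.1 and 0.035 N are
  exposed as `threshold` alternates for sensitivity analysis.
* **Energy.** Trapezoidal integration (`pracma::trapz`) from the start of
  the pull to the uprooting point, defined as the *last* downward
  crossing of the threshold after the peak (or the trace end). Traces are
  densely sampled, so higher-order quadrature is unjustified; on
  piecewise-linear synthetic traces with $\ge 1000$ samples the result
  matches the closed-form area to well under 0.1%.
* **Drops.** A drop is the decline from a local maximum of the load
  sequence to the next local minimum, after optional moving-median
  smoothing (off by default — whether traces should be smoothed before
  drop detection is genuinely open, so it is a switch, not a default).
  Boundary extrema are excluded on both sides: a monotone rise has no
  drops, and the terminal decline to zero is uprooting, not a drop.
  Only drops of at least `min_drop` (default 0.05 N) are reported.
* **Per-root normalisation.** Dividing a metric by total root length
  (RLD × container volume) yields the per-metre-of-root quantities on
  which lines are compared; RLD itself comes from dry mass × specific
  root length / volume.

The generator `gen_uprooting_trace()` realises the simplest member of
the damage-model family: constant $k_0$ to the peak and constant
softening slope $-h_0$ after it, so $x_u = x_p(1 + k_0/h_0)$ and the
energy is exactly $k_0 x_p x_u / 2$. Planted instantaneous drops are
placed on the *rising* branch, each followed by an elastic reload at
slope $2k_0$ back to the envelope. This placement is a design choice
forced by the drop definition: a peak-to-trough detector can only
recover a planted magnitude if the trace rises into the drop, whereas a
step superimposed on the declining branch merges into the terminal
decline. Real traces show drops on both branches; the generator trades
that realism for exact round-trip testability.

## Empirical erosion-reduction models

Flume runs expose planted soil boxes (0.25 m × 0.25 m surface) to
concentrated flow; run-off is captured for 5 s at 10 s spacing over at
most ~110 s. The per-interval detachment rate is sediment mass / (area ×
duration) and a box's ASD is the arithmetic mean over its intervals (the
alternative — total mass over total sampled time — differs only when
durations vary). Rates are normalised by the *extrapolated* zero-RLD
rate: bare boxes enter a fit of $ASD = A_0 e^{b\,RLD}$ at RLD 0 and all
rates are divided by $\hat A_0$, rather than by the bare-box mean alone.
When the response plateaus beyond a breakpoint (hairless roots), the
`extrapolate_below` argument restricts that extrapolation fit to the
exponential region.

Three response forms are available and are selected *explicitly* per
genotype rather than by automatic model selection (no selection criterion
is implied by the data design): pure exponential $e^{b\,RLD}$ for lines
with root hairs; piecewise — exponential up to a breakpoint (19 km m⁻³)
and a fitted constant above it — for hairless lines, not constrained to
be continuous at the breakpoint; and a smooth decay-to-plateau
$p + (1-p)e^{b\,RLD}$. All forms equal 1 at RLD 0: after normalisation
the intercept is forced rather than fitted. Least squares is on the
untransformed ratios with asymptotic standard errors
(`minpack.lm::nlsLM`; a log-scale fit is easy to apply upstream if
wanted).

Uncertainty follows the standard parametric Monte-Carlo recipe: the
fitted parameters are perturbed 10,000 times (reducible) from independent
normals centred on the estimates with sd equal to their standard errors,
and the pointwise 2.5/97.5% quantiles of the resulting curve family form
the 95% band. Draws use R's generator under a single user seed. Two
fitted curves are declared different at $P < 0.05$ wherever either point
curve leaves the other's band (`compare_bands()`).

## Cohesion back-calculation

Measured detachment rates convert to soil cohesion through the EUROSEM
runoff-detachment efficiency
$\beta = ASD / (B_D\, v_s\, C_{TC})$, evaluated in CGS units at this
equation's boundary (ASD in g cm⁻² s⁻¹, bulk density in g cm⁻³, settling
velocity in cm s⁻¹) with SI everywhere else in the package. The product
reading of the denominator is a documented interpretation — the three
factors are independently overridable — and the transport-capacity term
$C_{TC}$ is a required user input because its per-run derivation is
experiment-specific. The settling velocity of the median grain solves
$v_s = \sqrt{4 d_{50} (\rho_s - \rho_w) g / (3 C_D \rho_w)}$ with the
standard intermediate-Reynolds drag law
$C_D = 24/Re + 3/\sqrt{Re} + 0.34$ (no specific law is canonical here;
alternatives plug in via `cd`), iterated to a fixed point with tolerance
$10^{-8}$; for 16 µm grains the fixed point agrees with Stokes' law to
within a few percent and is independent of the starting Reynolds number.

Cohesion follows the empirical inverse $C = -\ln(\beta/0.79)/0.85$ kPa.
Efficiencies above 0.79 would imply negative cohesion; they are floored
at 0 kPa with a warning — a physical floor that keeps downstream
reinforcement fits defined. Root reinforcement is rooted-minus-bare
cohesion and is summarised by the origin-anchored model
$a\,\ln(RLD+1)$, fitted by least squares through the origin (bare soil
gains nothing by construction).

## Mechanistic erosion model

The mechanistic model predicts the erosion-reduction curve from first
principles plus two root-hair parameters. Its ingredients:

* **Bed shear stress.** A parabolic flow profile over a permeable bed
  gives $\tau = 3 g Q d_{50}^2 \sin(\mathrm{slope}) / (2 V k W)$ —
  about 21.6 Pa at the default 1 l s⁻¹ and 1 m s⁻¹.
* **True RLD.** Roots concentrate around each plant. One root system
  occupies a kite-shaped solid of revolution — two coaxial cones sharing
  a base of diameter equal to the lateral spread (0.1 m) with total
  vertical extent 0.1 m, volume $\pi\,\mathrm{spread}^2 D/12$. Total root
  length divided by the occupied volume (capped at the rooted slab once
  kites overlap) gives $RLD_T \ge RLD$. Under this two-cone choice the
  depth of maximum spread affects only the sub-volume split, not the
  total — a recorded limitation.
* **Enhancement function.** $\gamma(x) = M_{max}\tanh(M_1 x / M_{max})$
  in mm⁻¹: linear with initial rate $M_1$ at low true RLD, saturating at
  $M_{max} = M_1/M_2$. Cohesion extremes are
  $c_{max} = c_{bare}(1+\gamma R)$ at a stem and
  $c_{min} = c_{bare}(1+\gamma r)$ midway between stems, with the
  erosion depths $R$ (50 mm) and $r$ (23–42 mm observed; mid-range
  default 32.5 mm) in mm to match $\gamma$'s unit.
* **Eroded fraction.** Between plants the reinforced depth is
  interpolated sinusoidally,
  $\rho(x) = \tfrac{R+r}{2} + \tfrac{R-r}{2}\cos(2\pi x/L)$, and erosion
  occurs where $\tau + \mu N$ exceeds $c_{bare}(1+\gamma\rho(x))$. How
  that exceedance field aggregates into a measured detachment ratio is
  genuinely open; the package's reference interpretation is the eroded
  fraction of one spatial period, which has the closed form
  $F = 1 - \arccos(w)/\pi$ with
  $w = \big(u - \tfrac{R+r}{2}\big)\big/\tfrac{R-r}{2}$ clamped to
  $[-1,1]$ and $u = (\tau_{\mathrm{eff}}/c_{bare}-1)/\gamma$. The period
  length cancels, so plant spacing never enters; the closed form is
  verified against brute-force spatial integration to $10^{-6}$ on
  random parameter sets. The friction term $\mu N$ defaults to 0
  (surface erosion carries negligible normal stress) but remains
  configurable.

**Units at the Coulomb boundary.** Laboratory cohesion is a kPa-scale
quantity while fluid bed shear is Pa-scale; the comparison
$\tau_{\mathrm{eff}} > c$ is therefore made in a single declared unit
(Pa), with `c_bare` an *effective* surface shear-strength threshold, not
a vane cohesion. Only the dimensionless ratio $\tau/c_{bare}$ shapes the
predicted curve. The default `c_bare` = 2.4 Pa was chosen once so that
bare soil erodes under the default 21.6 Pa stress and the predicted
wild-type curve leaves 1 near 20 km m⁻³, consistent with where measured
reduction curves steepen; it was not revisited afterwards.

**Calibration.** `calibrate_enhancement()` minimises the maximum
relative error between predicted and observed ratios (the scale on which
the model's accuracy is naturally quoted; observations under 0.05 are
compared on that absolute floor so the objective stays defined where the
curve bottoms out). The minimisation is deterministic and staged: an
analytic inversion of the transition-region observations (each interior
ratio inverts through the closed form to a $\gamma_i$, and the series
expansion $\gamma/x = M_1 - (M_1^3/3M_{max}^2)x^2$ is regressed, then
polished by nonlinear least squares on the tanh law), a bounded
log-spaced grid scan, and Nelder-Mead refinement — first on a smooth
least-squares surface, then on the reported max-relative objective,
which is cliff-like where the curve reaches zero. The best candidate by
the reported objective wins.

**Identifiability.** In the experimental RLD range the tanh argument
$M_1 RLD_T/M_{max}$ is of order $10^{-3}$: saturation contributes only a
~$10^{-6}$ relative curvature to the curve. Noiseless curves carry that
signal far above double-precision noise, so the inversion stage recovers
both $M_1$ and $M_{max}$ to well under 1% — but a few percent of
measurement noise swamps it, leaving $M_{max}$ effectively
unidentifiable from noisy data under this aggregation model while $M_1$
remains well determined. The package reports whatever the bounded search
returns, and the tests assert only what the information content supports.
Relatedly, the sinusoidal-cohesion fraction has compact support in RLD —
flat at 1 until $\gamma R$ exceeds $\tau/c_{bare}-1$, zero once
$\gamma r$ does — so it cannot track a global exponential decay over the
full density range; the test suite computes this model-discrepancy
diagnostic (the best achievable sup-distance to an exponential when only
$\tau/c_{bare}$ is tuned) rather than asserting agreement.

## Synthetic data: what it does and does not emulate

All generators are pure functions of their parameters and seed
(byte-identical outputs under the same seed) and their outputs satisfy
the invariants of the consuming modules.

* `gen_detachment_cohort()` draws aerial masses lognormal (median 20 mg
  — a placeholder, as the true mass distribution of 5-day seedlings is
  not characterised) and detachment forces from a Weibull baseline
  (scale 0.02 N, shape 2) under a proportional-hazards construction on
  the force scale, $S(f) = S_0(f)^{HR}$, realised by inverse transform.
  Forces map to the first setting whose seedling-specific $F_c$ reaches
  them; survivors of the maximum setting are censored.
* `gen_uprooting_trace()` — see above; analytic peak, energy and drops.
* `gen_erosion_runs()` cycles boxes through the experimental planting
  densities (9–100 plants per box), places each box's RLD within its
  genotype's observed range (3–56, 8–48, 5–34 km m⁻³) by density rank
  with 15% lognormal jitter, and draws interval sediment masses around
  `bare_rate × ratio × area × duration` with mean-one multiplicative
  lognormal noise (σ = 0.3 by default — multiplicative because rates are
  positive with variance growing with the mean). `bare_rate` defaults to
  0.5 kg m⁻² s⁻¹, consistent with a 50 mm erosion depth over a ~110 s
  run at bulk density ~1.17 g cm⁻³.
* `gen_root_population()` draws SRL truncated-normal around the
  genotype/substrate means (e.g. wild type 0.63 m mg⁻¹ in clay).

What passing tests on these data do **not** show about real data: the
generators share the fitted functional forms with the analysis (an
exponential batch analysed with an exponential model), carry no spatial
correlation between intervals, no run effects or plate heterogeneity,
and no measurement error on RLD itself. Parameter-recovery results are
therefore statements about the pipeline's correctness, not about field
performance.

## Problem sizes

The shipped tests run the pipeline at the scale of the original design:
18-box erosion batches, 500-seedling cohorts for stochastic-ordering
checks, 20-point calibration curves, Monte-Carlo bands at 1,000–10,000
draws with 100-replicate nested coverage simulations, and brute-force
verification of the closed-form eroded fraction on 2×10⁶-point grids for
100 random parameter sets. The whole suite completes in well under two
minutes on a single CPU.
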