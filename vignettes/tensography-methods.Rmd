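---
title: "Shear-wave tensography: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-wave tensography: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tautr)
```

## The physical model

A focused ultrasound push deposits momentum in absorbing tissue through the
acoustic radiation force, $F = 2\alpha I / c_L$ (force density in N/m³ for
absorption $\alpha$ in Np/m, intensity $I$ in W/m² and compressional speed
$c_L$ in m/s). The displaced tissue relaxes by radiating shear waves, whose
speed carries the mechanical information: in an unstressed, isotropic,
linearly elastic medium the shear speed is $c = \sqrt{\mu/\rho}$, and in a
rod under axial tensile stress $\sigma$ the speed of a wave travelling
*along* the rod grows with the tension. `tautr` models the second effect in
its simplest useful form, a scalar out-of-plane displacement $u(x, z, t)$ in
the lateral ($x$, cranial–caudal) / axial ($z$, depth) plane:

$$\rho\,u_{tt} \;=\; \mu\,(u_{xx} + u_{zz}) \;+\; \beta\sigma\,u_{xx}
\;-\; \rho\gamma\,u_t \;+\; f(x, z, t).$$

The prestress contributes a membrane-like restoring term only in the
lateral direction, so the lateral phase speed is
$c_\mathrm{eff} = \sqrt{(\mu + \beta\sigma)/\rho}$ and **squared SWV is
exactly linear in tension** — the relationship the calibration layer fits
and inverts. The dimensionless coupling $\beta$ absorbs everything the
reduction leaves out (three-dimensional geometry, orthotropy, the
fluid–solid interface): $\beta = 1$ is the ideal stretched membrane, while
smaller values emulate stiffer constitutive behaviour where tension converts
to wave speed less efficiently. `beta_for_slope()` converts a measured
calibration slope into the equivalent coupling; a slope of
0.058 m²s⁻²g⁻¹ on a 5 mm-radius cord corresponds to $\beta \approx 0.46$.

Deliberately out of scope: orthotropic stiffness tensors, guided modes of a
fluid-immersed cylinder, Scholte waves at the fluid–solid boundary,
transducer aperture modelling and B-mode image formation. The package's
claims are therefore about the *method chain* — push, propagation,
time-to-peak estimation, calibration, diagnosis — not about predicting
absolute speeds in any particular cord.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| density $\rho$ | 1000 kg/m³ | soft tissue |
| shear modulus $\mu$ | 1932.1 Pa | relaxed SWV of 1.39 m/s at $\rho$ = 1000 |
| coupling $\beta$ | 1 | ideal membrane; calibrate with `beta_for_slope()` |
| damping $\gamma$ | 0 /s | the 2.3 ms window is too short for tissue viscosity to matter |
| cord radius | 5 mm | 4 kPa stress increments ↔ 32 g load increments |
| push intensity | 10⁷ W/m² (1000 W/cm²) | spatial-peak pulse-average intensity of a clinical-class push |
| push widths $\sigma_x, \sigma_z$ | 0.5 mm, 2 mm | focal zone much smaller than the cord, as for a focused linear array |
| push duration $\tau$ | 200 µs | sub-millisecond gate keeps push and tracking phases separable within 2.3 ms |
| absorption $\alpha$ | 0.5 dB/cm/MHz at 5 MHz (≈ 28.8 Np/m) | generic soft-tissue attenuation; scales amplitude only |
| grid | 30 × 20 mm, $h$ = 0.2 mm | matches the element size of the tracked region of interest |
| duration | 2.3 ms | long enough for the wavefront to cross the tracking window at the slowest speed |
| CFL safety | 0.9 | explicit 2D bound $\Delta t = 0.9\,h/(c_\mathrm{eff}\sqrt2)$ |
| sponge | 20 nodes, quadratic ramp | absorbs outgoing waves; constrained outer walls would reflect into the 2.3 ms window |
| tracking | 1.0–2.4 mm, 0.2 mm steps, at focal depth | see below |
| diagnosis threshold | 1.76 m/s | zero-tension baseline of the simulation-scale calibration |
| curvature cutoff | 5 % | see below |
| min sub-samples | 30 | images with fewer usable datapoints are discarded |

Amplitude-scale parameters ($I_0$, $\alpha$) do not influence any speed,
fit or diagnosis — the model is linear — so they matter only for inspecting
fields.

## Numerical choices

**Scheme.** Explicit central differences in time and space (leapfrog on the
5-point Laplacian with the anisotropic $\beta\sigma$ term folded into the
$x$ coefficient). Damping is applied with the standard
$(1 \pm \eta\Delta t/2)$ splitting, which keeps the scheme second-order.
The push gate is weighted by its fractional overlap with each time step so
the injected impulse is independent of $\Delta t$. A divergence guard
aborts with the offending step number if any displacement exceeds 10⁶ times
the largest push-phase displacement.

**Boundaries.** Quadratically graded sponge layers (20 nodes) with peak
damping $4c_\mathrm{eff}/(w h)$; the outermost nodes are clamped. Residual
edge amplitudes are below 10⁻³ of the field maximum at the end of the run.

**Tracked signal and window.** Time-to-peak is defined on the magnitude of
the *particle velocity* (frame difference), not the raw displacement, and
tracking starts 1.0 mm (two lateral push-sigmas) off axis. Both choices are
accuracy-driven and were measured on this simulator: the displacement peak
at positions closer than ~2$\sigma_x$ coincides with the end of the push
(direct forcing, not wave arrival) and the slowly relaxing near-field
displacement plus the diffraction of the axially extended source inflate
displacement-tracked speeds by 6–8%. With velocity tracking from 1.0 mm the
estimate agrees with the analytic $\sqrt{(\mu+\beta\sigma)/\rho}$ to within
1% at every load in the 0–256 g schedule (and within 0.8% when the grid
spacing is halved). A `signal = "displacement"` switch preserves the
alternative. Sub-frame arrival times come from three-point parabolic
interpolation around the discrete peak; without it, frame quantization
biases the distance-versus-time slope at coarse output rates. Smoothing of
the wavefront trace is off by default and left to the user.

**Calibration.** `fit_squared_swv()` regresses $v^2$ on load *in grams*
(not stress), so slopes are directly comparable to benchtop protocols where
the load is what is controlled; `grams_to_stress()` (with
$g_0 = 9.80665$ m/s²) serves the physics side. Replicates enter as
individual points rather than load means. The 95% prediction band uses the
exact $t$-quantile formula
$\hat y \pm t_{0.975,n-2}\, s\sqrt{1 + 1/n + (x-\bar x)^2/S_{xx}}$.
Tension inversion clamps negative results to 0 g with an
`out_of_calibration` flag: a speed below baseline means "no tension" under
the model, not a negative load.

**A documented inconsistency.** The simulation-scale calibration intercept
(baseline 1.76 m/s from a squared intercept of 3.108 m²s⁻²) exceeds the
directly simulated relaxed speed of 1.39 m/s. That is a property of
fitting a straight line to data with slight curvature near zero load; the
linear model is retained as the method specifies, and the package reports
both numbers rather than reconciling them.

## The diagnostic pipeline

Sub-samples marked out-of-plane are dropped; an image needs at least 30
usable sub-samples to survive (exactly 30 is kept — the rule discards
"fewer than 30"). An image is called *stretched* iff its median SWV is
strictly above the threshold; ties go to relaxed. Per case, the treated
(POST) state is the FULL checkpoint unless its mean relative curvature —
$(\mathrm{arc}/\mathrm{chord} - 1)\times 100$ on the imaged centerline —
exceeds the exclusion cutoff, in which case MID substitutes; a case with an
excluded FULL and no MID is reported as failed QC and the remaining cases
proceed. The numeric cutoff is not fixed by any published criterion, so the
default (5%) is an explicit, configurable choice sized so that the straight
segments of a healthy cord pass easily while a visibly slack cord
(curvature ≳ 6–10%) is excluded.

Per-case PRE/POST differences use Welch's $t$ on the pooled sub-sample
datapoints (recorded $\alpha$ = 0.001, reported raw — no multiplicity
adjustment across cases, and the report says so). Image-wise comparisons
within a case use classical one-way ANOVA ($\alpha$ = 0.05) with
Tukey–Kramer post hoc contrasts (studentized range with the unequal-$n$
standard error, $\alpha$ = 0.001). The ROC layer is written in-package to
pin down its conventions — candidate thresholds at midpoints between
consecutive distinct observations, trapezoidal AUC (≡ Mann–Whitney
concordance with ties at ½), Youden ties broken toward the lower
threshold — with the AUC interval by DeLong's method by default (a seeded
2000-resample percentile bootstrap as the alternative, since the tools
used for published ROC analyses rarely disclose their method). The test
suite cross-checks AUC and the DeLong interval against `pROC` and against
brute-force concordance.

## What the synthetic generators emulate

`generate_tension_sweep()` emulates a benchtop calibration: baselines at 0
and 1 g, then 5–250 g in 5 g steps, three acquisitions per load (156 rows).
Noise is Gaussian *on squared SWV*, which keeps the linear calibration
model exact in expectation. Defaults are anchored to the benchtop scale of
the method: slope 0.053 m²s⁻²g⁻¹, intercept 12.658 m²s⁻² (so the 250 g
speed is ≈ 5.09 m/s), and noise SD 0.9 m²s⁻² — the level at which the
schedule-wide $R^2$ sits near 0.95, matching the scatter such preparations
show.

`generate_case_series()` emulates a six-case intraoperative series:
PRE/MID/FULL checkpoints, 3–6 images per checkpoint, 40–120 sub-samples per
image (a fixture option reproduces a published ten-image count pattern
verbatim), sub-sample SWV normal around checkpoint means with a lognormal
alternative for heavier right tails. The default means (PRE 2.3, MID 1.55,
FULL 1.45 m/s, SD 0.25) are free parameters chosen to straddle the 1.76 m/s
threshold the way a successful shortening series does; they are not
estimates of any patient population. The last third of cases receives
FULL-checkpoint curvature above the exclusion cutoff (truncated below at
6%) so the MID-as-POST fallback path is always exercised.

What passing tests on these generators shows: the pipeline's QC, selection,
testing and ROC machinery behaves correctly on data with the stated
structure, and the calibration recovers known parameters at realistic noise.
What it cannot show: anything about real acquisition physics — probe
motion, saline irrigation, reflective artifacts, out-of-plane geometry,
inter-operator variability — or about clinical performance figures, which
depend on patient data the package does not contain.

## Problem sizes

The default grid is 151 × 101 nodes; a nine-load sweep integrates roughly
10²–10³ time steps per load and completes in a few seconds. The test suite
uses 100-seed Monte-Carlo batches for coverage/power properties and 10⁴
draws for prediction-band coverage; these sizes give Monte-Carlo standard
errors comfortably below the tolerances being asserted.

## Known limitations

* The 2D scalar reduction cannot represent anterior–posterior speed
  asymmetry, depth-dependent beam shape, or any guided-wave dispersion; its
  $\beta$ is a calibration knob, not a measured material constant.
* Time-to-peak assumes a single outgoing wavefront; strongly reverberant or
  multi-path fields would need directional filtering, which is not
  implemented.
* The curvature metric is global (end-to-end); locally kinked centerlines
  with straight chords can evade it.
* Centerlines are supplied, not extracted from images.
* The clinical statistics assume sub-samples are exchangeable within an
  image; spatial correlation along the cord would make the per-case Welch
  tests anticonservative, one reason the recorded $\alpha$ is 0.001.
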