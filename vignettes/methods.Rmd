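---
title: "Models and numerical methods behind hemoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind hemoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoflow)
```

`hemoflow` is a desk-scale pipeline for size-dependent aneurysm
hemodynamics: it fits a patient-specific Casson blood model, builds and
measures synthetic dome geometries, solves pulsatile generalized-Newtonian
flow in a 2D channel-and-dome analog of the vascular anatomy, derives the
dome-resolved hemodynamic metrics, classifies the flow pattern, and
compares small (height ≤ 5 mm) versus large (> 5 mm) groups. This vignette
explains each model, the parameters that matter, the numerical choices, and
what the synthetic study can and cannot show.

## The Casson blood model

Whole blood is shear-thinning with a small yield stress. The Casson law

$$\sqrt{\tau} = \sqrt{\tau_y} + \sqrt{k\,\dot\gamma}, \qquad \tau > \tau_y,$$

with $\dot\gamma = 0$ below the yield stress, rearranges to the apparent
viscosity

$$\mu(\dot\gamma) = \left(\sqrt{\tau_y/\dot\gamma} + \sqrt{k}\right)^2 .$$

* $\tau_y$ (Pa) — yield stress; physiologic whole blood sits around
  0.002–0.02 Pa. Below it blood behaves as a solid (plug flow).
* $k$ (Pa·s) — the high-shear plateau. We take $k$ in Pa·s so that
  $\mu \to k$ as $\dot\gamma \to \infty$, matching the measured plateau of
  a viscometer curve (3–5 cP). (The alternative convention, $k$ in
  $(\mathrm{Pa\,s})^{1/2}$, would make $\mu \to k^2$; the plateau-matching
  convention is the one under which the fitted parameters are directly
  comparable to reported centipoise values.)
* `shear_floor` (default 1 s⁻¹) — $\mu(\dot\gamma)$ diverges as
  $\dot\gamma \to 0$, so evaluation clamps the shear rate at the lowest
  rate a scanning capillary viscometer calibrates (1 s⁻¹). This keeps the
  solver bounded and never extrapolates the constitutive law below the
  measured range. Behavior below 1 s⁻¹ is therefore a modeling choice, not
  a measurement.

**Fitting.** `fit_casson()` converts each measurement to a stress
$\tau_i = \mu_i \dot\gamma_i$ and regresses $\sqrt{\tau}$ on
$\sqrt{\dot\gamma}$ — the space in which the law is exactly linear, so the
fit is deterministic with no initialization. Viscometer noise is
multiplicative ($\mu_i$ observed as $\mu(1+\varepsilon)$), which makes
$\mathrm{Var}(\sqrt{\tau_i}) \propto \tau_i$; the regression is therefore
weighted by $1/\tau_i$. On noiseless data the weighted and unweighted fits
are identical (both exact); at 2% noise the weighting is what keeps the
worst-case yield-stress error below 5% across the physiologic range — the
unweighted fit lets the high-shear points dominate and degrades
$\tau_y$ recovery several-fold. A negative intercept (possible for nearly
Newtonian noisy data) is clamped to $\tau_y = 0$ with $k$ refit through the
origin.

**Analytic oracle.** The closed-form Casson tube flow
(`casson_tube_flow_rate()`),
$Q = \frac{\pi G R^4}{8k}\left(1 - \tfrac{16}{7}\xi^{1/2} + \tfrac43\xi -
\tfrac1{21}\xi^4\right)$ with $\xi = \tau_y/\tau_w$, plus the two-zone
plane-channel solution used in the tests, give independent references the
solver must reproduce.

## Geometry: the spherical-cap dome family

Synthetic domes are spheres of radius $R$ clipped by the neck (ostium)
plane at signed offset $s$ from the center: height $H = R - s$, neck
radius $\sqrt{R^2 - s^2}$, width $W = 2R$ for supra-hemispherical caps
($s < 0$) and $W = O$ otherwise. `measure_morphometrics()` works on any
triangulated dome with a neck-plane annotation:

* the height axis is the neck-plane normal (width is then unambiguous as
  the longest diameter orthogonal to it, measured over dome vertices
  projected into the plane);
* the ostium polygon is the mesh boundary loop ordered angularly about its
  centroid, with the shoelace area — robust for the star-shaped necks all
  generated geometries have;
* width is measured on the dome side only; automatic neck detection for
  arbitrary clinical meshes is out of scope (the neck plane is an input).

The generator inverts the cap closed forms: given sampled $(H, W, O)$ it
finds the least-squares cap, weighting the height residual 4× so the
fitted height stays on its group's side of the 5 mm cutoff (the three
targets are not exactly cap-consistent, and height *is* the grouping
variable).

## The 2D flow problem

Full 3D patient-specific CFD is replaced by a mid-plane analog with
identical physics: a straight channel of width equal to the parent artery
diameter (default 4 mm, 10 diameters long) with the dome as a circular
segment opening through a neck gap on one wall. The momentum equation

$$\rho\left(\frac{\partial u}{\partial t} + u\cdot\nabla u\right)
  = -\nabla p + \nabla\cdot\big(\mu(\dot\gamma)\nabla u\big), \qquad
  \nabla\cdot u = 0$$

is solved with:

* **density** $\rho = 1060$ kg/m³ (standard whole blood) and **period**
  $T = 1$ s (60 bpm) — neither is part of the measured protocol, both are
  standard;
* **inlet**: parabolic profile whose mean speed is $Q(t)/A_\text{inlet}$
  with the patient's inlet area ($\approx (\pi/4)d^2 \approx 12.6$ mm²),
  so speeds are physiologic (mean ≈ 0.2 m/s) despite the 2D reduction;
  the waveform is a single harmonic
  $Q(t) = \bar Q(1 + A\sin 2\pi t/T)$ about the published mean
  $\bar Q = 2.6$ mL/s with relative amplitude $A = 0.5$ — the simplest
  shape with well-defined peak-systole ($t = T/4$) and end-diastole
  ($t = 3T/4$) instants; richer waveforms can be substituted;
* **walls**: rigid, no-slip; **outlet**: traction-free;
* **protocol**: four cardiac cycles, fields stored from the second;
  within each time step the viscosity/advection nonlinearity is
  Picard-iterated to a relative velocity increment below 0.01 with a cap
  of 50 iterations (steps that hit the cap are flagged, never hidden).

### Discretization

A uniform staggered (MAC) grid with cell flags (parent / dome / solid)
represents the geometry; the dome boundary is therefore stair-stepped,
which is why all dome-wall quantities are validated against analytic
straight-wall solutions and treated as 2D analogs elsewhere. Each step
solves implicit momentum predictors (first-order upwind advection with
frozen advecting velocity, variable-viscosity diffusion in
$\nabla\cdot(\mu\nabla u)$ form — the transpose term vanishes identically
for the unidirectional validation flows) followed by an **incremental
pressure-correction** (Van Kan) projection: the predictor includes the
current pressure and the Poisson solve updates its increment. The
incremental form matters: the non-incremental variant leaves an
$O(\Delta t\,\nu/h^2)$ splitting error that acts like wall slip and grows
with the implicit step. With it, the discrete steady channel profile is
the exact discrete parabola (Poiseuille $L_2$ error 0.13% at
$h = 0.2$ mm) and mass is conserved to solver precision at every stored
snapshot.

Wall shear rate uses the ghost-consistent two-point estimate
$\dot\gamma_w = 2|u_1|/h$: the mirror-ghost wall treatment shifts the
resolved parabola by $G h^2/(8\mu)$, and this estimator cancels that shift
exactly (errors vs the analytic plane-channel wall stress: 0.4%
Newtonian, 1.6% Casson at $h = 0.2$ mm). The scalar shear rate everywhere
else is the standard generalized-Newtonian invariant
$\sqrt{2\,D\!:\!D}$.

Defaults: $\Delta t = T/200$, grid spacing 0.25 mm. The steady solver
pseudo-time-marches the same scheme with a step capped at the cell
viscous time $\rho h^2/k$ (the projection's pressure update scales with
$1/\Delta t$, so an unbounded step stalls convergence at low flow rates).

## Hemodynamic metrics and flow patterns

Per patient: dome-averaged shear rate and apparent viscosity at PS and ED
("dome volume" = dome area in 2D); instantaneous wall shear stress
$\mu(\dot\gamma_w)\dot\gamma_w$; TAWSS $= \frac1T\int_0^T |WSS_i|\,dt$ by
trapezoid with periodic closure of the one-cycle storage; minimal and
maximal WSS as the global extrema over dome wall samples × cycle times
(the spatial-average-of-temporal-extrema alternative is available behind
`spatial_average = TRUE`); the per-patient TAWSS scalar is the
area-weighted dome-surface average.

Flow complexity counts recirculation zones as interior local extrema of
the stream function inside the dome whose deviation from the dome-wall
streamline exceeds 1% of the dome's maximum deviation — a reproducible
surrogate for visual zone counting that suppresses numerical micro-eddies
(raising the threshold can only lower the count). One zone or none is
"simple", two or more "complex"; the zero-zone case does not arise in the
visual scheme and is mapped to "simple". The inflow jet is classified at
peak systole by seeding the fastest decile of ostium inflow, tracing
streamlines to their first dome-wall impingement, and calling the jet
"concentrated" when the median impingement lies within ±30° of the tip
direction (the neck normal through the apex); streamlines that circle back
out through the neck without impinging are wall-following, i.e.
"diffused". Both the decile rule and the ±30° window are package
conventions for a criterion the visual scheme leaves qualitative.

## Group statistics

Each variable is compared between groups with a Shapiro–Wilk gate at 0.05
per group: both normal → two-sided pooled-variance (Student) t test (Welch
behind `var_equal = FALSE`); otherwise a two-sided Mann–Whitney rank-sum
test, computed by exhaustive enumeration of all group assignments for
pooled $n \le 20$ (exact even under ties, via midranks; the permutation
distribution of the rank sum is symmetric, so the two-sided p is the tail
probability of $|W - \mathbb E W|$) and by the tie-corrected normal
approximation above that. Degenerate comparisons (all values identical)
report $p = 1$ with a flag. Derived ratios follow the printed conventions
exactly: percent increases are truncated to one decimal, fold changes
rounded half-up. No multiple-testing correction is applied, matching the
reporting protocol.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws 16 small + 5 large patients. Morphology is
calibrated: heights from truncated normals at the reported group means/SDs
(3.4 ± 0.8 mm vs 6.2 ± 2.4 mm, respecting the cutoff), widths and ostia
conditionally (positive, $W \ge O$). Rheology is *not* patient-published
anywhere, so $\tau_y \sim U[0.002, 0.02]$ Pa and
$k \sim U[0.003, 0.005]$ Pa·s were chosen once as a physiologic band that
reproduces the qualitative shape of measured whole-blood curves; each
patient gets a 50-point synthetic viscometer curve at 2% multiplicative
noise (the density of a scanning capillary sweep) which is then *refit*,
so the study consumes fitted, not true, parameters — exercising the
rheology pipeline end to end. Everything is deterministic under one master
seed with per-patient derived seeds.

Only morphology is calibrated; the hemodynamic magnitudes must emerge from
the solver. They do so directionally, and that is the honest limit of the
desk-scale study:

* **What reproduces robustly**: larger domes have lower dome-averaged
  shear rate, higher dome-averaged apparent viscosity and lower TAWSS at
  every seed tried; the shear-rate contrast is statistically significant
  at the 0.05 level in every run we have examined.
* **What is seed-sensitive**: significance of the viscosity contrast with
  $n = 16$ vs 5. The per-patient Casson draw is independent of size group
  (as in the real cohort, where blood properties are not determined by
  aneurysm size), and at 2D desk-scale shear levels that between-patient
  rheology variance competes with the size effect; viscosity p-values
  range from below 0.01 to ~0.4 across master seeds. TAWSS significance is
  similarly marginal.
* **What cannot reproduce by construction**: the absolute magnitudes of
  the reported tables. The 2D mid-plane analog at coarse grids produces
  dome shear rates of tens of s⁻¹ rather than hundreds, and
  correspondingly different WSS scales; the patient-level geometries and
  rheology behind the published per-group values are not public, so only
  directions and the printed derived ratios are quantitative targets.

Problem sizes used throughout the tests and the acceptance script are the
"fast" preset — 0.5 mm grid, $\Delta t = T/50$, two cycles reporting the
second, 0.3 mm dome-mesh resolution — chosen so the full 21-patient study
is a routine desk run; the solver-validation cases use the finer 0.2 mm
grid where the analytic-oracle tolerances (1–2%) are met with margin.

## Known limitations

* The stair-stepped dome wall limits pointwise accuracy of dome-wall WSS;
  straight-wall WSS is validated to 2%, dome-wall values are comparative.
* First-order upwind advection is diffusive at the cell Péclet numbers of
  the coarse preset; metrics are reported as 2D analogs, not absolute
  predictions.
* The single-harmonic waveform has one systolic peak; physiologic
  waveforms (dicrotic notch) shift PS/ED timing but not the cycle-mean
  machinery, and can be passed through a custom `solver_config()`.
* Neck-plane detection, bifurcation geometries, vessel curvature,
  fluid–structure interaction and 3D vortex criteria are out of scope.
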