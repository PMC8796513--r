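---
title: "A reduced-order model of intrathecal tracer transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of intrathecal tracer transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csftransport)
```

## What the model is

`csftransport` simulates the 3-h fate of a tracer bolus injected into
the cerebrospinal fluid at a chosen site — lumbar puncture (LP),
cisterna magna (CM) or the left lateral ventricle (ICV) — under eight
preset injection/physiology scenarios, and quantifies the outcome as
spatial–temporal pharmacokinetics (per-cell and per-region AUC, C_max,
T_max) plus simulation-vs-experiment agreement statistics.

The physical premise: oscillatory CSF motion (cardiac, ~1 mL stroke
volume at 0.9 s; deep respiration, ~6 mL at 11.7 s) produces no net
flow, but in the convoluted subarachnoid geometry it leaves behind (i)
a small cycle-averaged *steady-streaming* velocity field, on the order
of 0.1 mm/s, and (ii) a strong shear-augmented *effective dispersion*.
These — not molecular diffusion, which is negligible on this horizon
and is excluded — govern how an intrathecal dose spreads. A full 3D
resolution of that mechanism is cluster-scale CFD; this package
collapses it onto the neuraxis with a calibrated 1D closure so that a
scenario runs in a few seconds on one CPU.

## Governing equation and numerics

On the axial grid (z = 0 at the cranial end, 76 cm long, 380 µm cells,
cross-sectional area `A(z)`), the cross-sectionally averaged
concentration obeys

$$\frac{\partial (A c)}{\partial t} + \frac{\partial (Q c)}{\partial z}
 = \frac{\partial}{\partial z}\!\left(A D_{\mathrm{eff}}
   \frac{\partial c}{\partial z}\right) + s(z, t),$$

with face flux `Q` the sum of

* ventricular production throughflow (0.4 mL/min total, split equally
  between the lateral ventricles, routed through the well-mixed
  lateral → third → aqueduct → fourth compartment chain into the basal
  cistern, and leaving at the cranial opening, the model's elimination
  route);
* the transient injected-volume flux toward the cranial outlet during
  the bolus and flush windows (this is how bolus volume and flush rate
  influence transport); and
* the solute steady-streaming drift `A u_ss` described below.

Numerics: operator splitting with explicit upwind advection under a van
Leer flux limiter and implicit (backward Euler) dispersion via a
pre-factorized tridiagonal solve, implemented in C++. The internal step
is 0.05 s (far inside the advective CFL limit at the default grid; the
solver refuses a step that violates it, naming the offending step);
outputs are resampled to 900 ms columns to match the standard matrix
layout. The scheme is conservative by construction: every run returns a
mass ledger (injected, in-model, out-flowed) whose closure error is
~1e-13, and the limiter keeps concentrations non-negative. Halving both
the grid spacing and the time step changes the 3-h exposure profile by
less than 2% (this is asserted in the test suite).

## The closure and its calibration

With `u_osc,i(z) = peak|Q_i| · e(z) / A(z)` the oscillatory velocity
amplitude of waveform component `i` (angular frequency `ω_i`), the two
closures are

$$D_{\mathrm{eff}}(z) = D_{\mathrm{base}} + \alpha\, m(R(z))
  \sum_i \frac{u_{\mathrm{osc},i}(z)^2}{\omega_i},
\qquad
u_{\mathrm{ss}}(z) = -\,s_0\, m(R(z)) \sum_i
  \frac{u_{\mathrm{osc},i}(z)^2}{\omega_i\, L_{\mathrm{ref}}},$$

a Taylor/Watson-type quadratic dispersion closure and the classic
second-order steady-streaming velocity scale over a geometric feature
length, both modulated by the same per-region factor `m` (secondary
flows around nerve roots and area changes drive both phenomena). The
amplitude envelope `e(z)` is 1 cranial of the foramen magnum — the
waveform is referenced to the C2–C3 level — and decays linearly to zero
at the closed sacral end, where no oscillatory flux can cross the wall.
The drift is directed cranially, the direction of net tracer motion
observed for spinal injections.

Tunable constants (all exposed in `default_calibration()`):

| constant | default | units | meaning |
|---|---|---|---|
| `alpha` | 0.2 | – | dispersion closure coefficient |
| `streaming_scale` | 0.053 | – | streaming drift coefficient |
| `L_ref` | 1 | cm | geometric feature length |
| `D_base` | 1e-5 | mm²/s | numerical floor (molecular diffusion excluded) |
| `m(region)` | 2 / 2 / 3 / 0.75 / 0.05 / 1 / 0.5 | – | cortical+basal / cerebellum(=3) / cervical / thoracic / lumbar / sacral |

The constants were calibrated once, against transport anchors reported
for this system — a cranially directed lumbar tracer front of ~31 cm/h,
cervical steady streaming up to three times the lumbar value, a ≥2-log
cranial-exposure separation between CM/ICV and LP routes, ~3% of an ICV
dose still resident in the injected ventricle after 3 h, and the
published cranial/spinal exposure values — and then frozen. The low
thoracic factor encodes the reported deceleration of cranially moving
tracer in the mid-thoracic spine; it is what keeps a lumbar dose spinal
(the 2–3-log cranial/spinal separation) while CM and ICV doses, which
start cranial of the barrier, produce three-orders-higher cranial
exposure.

Two calibration anchors deserve honesty:

* **Front speed.** The ~31 cm/h figure describes the early cranial
  front (lumbar injection site to the mid-cervical level within
  60–90 min, i.e. distance over time). The package's `front_speed()`
  implements a stricter definition — the least-squares slope of the 5%
  -of-instantaneous-maximum front position over 0–120 min. Under that
  definition the surrogate yields ~7 cm/h, because the front reaches
  the thoracic slow-down region within minutes and then creeps; in a
  *linear* 1D closure a sustained 31 cm/h least-squares front is
  incompatible with the 2-log cranial separation (a front that fast
  must carry bulk tracer with it). The 3D mechanism escapes this
  because dilute tracer travels in fast streaming channels that the
  cross-sectional average does not represent. We keep the strict
  definition, report the discrepancy, and do not re-tune.
* **Regression agreement.** The per-scenario R² between simulation and
  bench experiment depends on the spatial variance structure of the
  real 3D fields; a 1D surrogate paired with a synthetic bench replica
  reproduces the *limits of agreement* (below) but not those R² values.

## Scenario presets

The eight presets (`scenario_from_table()`, also shipped as YAML files
under `inst/extdata/scenarios/`) hold the delivered tracer dose constant
at 0.425 µmol: baseline LP (5 mL at 5 mL/min, L3/4, stroke volume
1 mL), CM and ICV at the same protocol, 5X bolus rate (25 mL/min), 3X
bolus volume (15 mL at tracer fraction 1/3), 2X stroke volume, 5 mL
flush (tracer-free, 5 mL/min, starting immediately at the end of the
bolus), and deep respiration (10 mL bolus at tracer fraction 0.5, with
the composite waveform). Axial anchors, chosen once because no table of
vertebral positions is available: foramen magnum 15 cm from the cranial
end, LP needle at 60 cm, CM at 15 cm, ICV into the left-lateral-ventricle
compartment (11 mL, physiologic).

The tracer stock concentration (85 µM) is the one free dosimetric
constant; it was fixed from the reported agreement statistics (a
±1.20 µM limit of agreement described as 1.41% of dynamic range implies
a pooled concentration span of ~85 µM, attained at the needle tip at
the end of the bolus). The cross-sectional area profile is
piecewise-linear with a total CSF volume of 317 mL, inside the
physiologic 250–400 mL range.

## What the synthetic-data generator emulates

`analytic_pulse_matrix()` evaluates the closed-form advection–dispersion
Green's function (image sources for the reflecting ends, truncated at
three reflections — an error far below output formatting precision for
the parameter ranges used) on the standard matrix layout; because no
solver is involved it serves as an independent oracle for the solver,
the PK metrics and the parameter-recovery estimator.
`make_pseudo_experiment()` adds i.i.d. Gaussian noise clipped at zero —
an optical concentration readout cannot go negative — which is the
noise model used in place of the request-only bench data. The noise
level for a given scenario is set from the published 95% limits of
agreement (±1.20/±1.15/±0.85 µM for LP/CM/ICV); `noise_sd_for_loa()`
inverts the clipped-noise variance in closed form so the stand-in
reproduces the stated level exactly. What passing these tests shows is
that the *analysis pipeline* (pairing, regression, Bland–Altman, PK
metrics, parameter recovery) is correct and that the surrogate's
transport is quantitatively calibrated; it does not show that a 1D
closure reproduces 3D spatial structure (hemispheric asymmetry, needle-
tip fields, the flange artifact near the foramen magnum in the bench
model).

`recover_transport_parameters()` estimates (u, D) from a single-pulse
matrix by the drift and growth of the pulse's centroid and spatial
variance. Per column the variance is taken from a Caruana quadratic
log-fit over the cells above 20% of the pulse peak (exact for a clean
Gaussian, immune to the positive background that zero-clipped noise
leaves in the tails), restricted to columns whose pulse is well inside
the domain with peak ≥25 noise SDs; windowed moments are the fallback
for near-delta pulses.

## Numerical and design choices

* T_max ties break to the earliest attainment.
* Regional AUC is the AUC of the region-averaged time course (identical
  to the mean of per-cell AUCs by linearity; the former is primary).
* The cranial/spinal split for compartment summaries is the foramen
  magnum position (15 cm), a single configurable number; the acceptance
  checks report the sensitivity of cranial AUC to ±2 cm.
* Bland–Altman limits use the population SD by default (`sd_type =
  "sample"` switches; the difference is negligible at 10⁴–10⁵ pairs),
  and "dynamic range" defaults to the pooled max−min of the two
  matrices, making the printed percentages recomputable.
* Regression direction is fixed: numerical on bench reference.
* The deep-respiration composite's stroke volume is reported for the
  respiratory band: one half the integral of |Q| over the breath counts
  every cardiac back-and-forth (~13 mL) if applied to the raw
  composite, so `respiratory_stroke_volume()` extracts the slow
  component (stored at construction, or by a one-cardiac-period moving
  average) and returns ~6 mL at defaults. The cardiac surrogate is a
  two-harmonic skewed sine, `sin θ + (1/3) sin 2θ`, whose stroke volume
  is exactly `A T / π` independent of the skew; the skew puts the
  systolic peak at ~4.1 mL/s per 1 mL stroke volume, consistent with
  PCMRI waveforms, and makes the 40%-scaled respiratory component's
  stroke volume 6.0 mL.
* Ventricular compartments are well-mixed and strictly feed-forward
  (production blocks retrograde movement); a CM dose therefore shows
  zero ventricular exposure in this model, whereas the 3D system shows
  a minuscule fourth-ventricle penetration.
* Problem sizes: scenario runs use the full 2000-cell grid at the 0.05 s
  internal step; test-suite property checks run on coarser grids
  (380–2000 µm) chosen so the whole suite completes in a few minutes.

## Known limitations

1D cross-sectional averaging cannot represent hemispheric (left/right)
asymmetry, anterior/posterior streaming channels, or 3D needle-tip
fields; the ICV axial matrix never exhibits the ~85 µM needle-tip peak
because that peak lives inside the ventricle compartment. Tissue and
perivascular absorption, CSF pulsatility changes with posture or
pathology, compliance and fluid–structure interaction are out of scope.
The closure constants are calibrated to one published system; applying
the model to a different anatomy requires re-anchoring them.
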