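---
title: "Sarcomere length effects on left-heart mechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sarcomere length effects on left-heart mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcomech)
```

This vignette documents the models implemented in `sarcomech`, the
conventions and parameter choices behind them, and what the package's tests
do and do not establish.

## The constitutive models

### Passive myocardium

Passive tissue follows the orthotropic Holzapfel-Ogden strain-energy
decomposition: an isotropic exponential matrix term in the first deviatoric
invariant, exponential-quadratic fiber and sheet reinforcement terms in the
squared stretches `I4f`, `I4s`, a fiber-sheet coupling term in `I8fs`, and a
volumetric penalty `psi_vol = (1/D)((J^2-1)/2 - log J)`. The reinforcement
terms are tension-only: they contribute only when the corresponding `I4`
exceeds 1, the standard convention that prevents fictitious compressive
fiber stiffness. The verification parameter set is `a = 0.004`, `b = 8`,
`a_f = 0.005`, `b_f = 5`, `a_s = 0.002`, `b_s = 2` (moduli in MPa). No
published value exists for the coupling modulus, and the coupling invariant
is identically zero in every axis-aligned deformation used here, so
`a_fs = 0` by default.

Under homogeneous biaxial stretch along the material axes with traction-free
sheet-normal faces and exact incompressibility
(`lambda_n = 1/(lambda_f lambda_s)`), the Cauchy stresses have closed forms
(`cauchy_biaxial()`). These are verified against `numeric_stress_oracle()`,
which differentiates the constrained strain energy by central differences in
log-stretch; eliminating `lambda_n` through the constraint automatically
subtracts the reaction pressure of the traction-free direction, so the two
routes must agree to O(h^2). A single reduced-integration hexahedron under
homogeneous displacement control is mathematically the point-wise
constitutive response, so this oracle plays the role a one-element
finite-element solve would play, without the explicit-dynamics machinery.
The default report tolerance is 1e-5 relative with a 1e-9 MPa absolute
floor; the small kink of the tension-only terms at `I4 = 1` degrades the
central difference from O(h^2) to O(h) exactly at stretch 1, which the
absolute floor absorbs.

### Active myocardium

Active fiber stress follows the time-varying-elastance law: a calcium
factor `Ca0^2 / (Ca0^2 + ECa50^2)` times a `1 - cos(omega)` waveform that
rises over `t0` seconds and relaxes over `t_r` seconds. The half-maximal
calcium concentration `ECa50 = Ca0_max / sqrt(exp(B (L - L0)) - 1)` falls as
the sarcomere lengthens beyond the zero-tension length `L0` - the
Frank-Starling gain. The relaxation duration is affine in length,
`t_r = m L + b`. Defaults: `T_max = 0.1` MPa, `Ca0 = Ca0_max = 4.35`,
`B = 4750` per mm, `t0 = 0.1` s, `m = 1048.9` s/mm, `b = -1.429` s,
`Lr = 1.85` um, `L0 = 1.58` um.

Two conventions deserve emphasis:

* **Units.** The printed constants are mutually consistent only if lengths
  are in millimetres and times in seconds internally: `B * SLD =
  4750 * 0.27e-3 = 1.2825` gives a finite sensitivity, and `t_r(1.85 um) =
  1048.9 * 1.85e-3 - 1.429 = 0.511` s matches a 1-s beat. The API accepts
  sarcomere lengths in micrometres and converts internally; this is tested.
* **Waveform closure.** The relaxation phase maps `[t0, t0 + t_r)` onto
  `[pi, 2 pi)`, so `1 - cos` closes to zero continuously at the duration of
  contraction `DOC = t0 + t_r`. Both `ECa50` and `t_r` are evaluated at the
  *current* length `L(E_ff(t))` - the law is written as a function of the
  instantaneous fiber strain, and an isometric twitch (the verification
  case) is unaffected by the choice because its strain is constant.
* **Below threshold.** For `L <= L0` no finite `ECa50` exists; active
  stress is defined as 0 rather than an error so that organ-level sweeps
  remain well-posed.

Two closed forms follow directly and anchor the tissue-level analysis: the
isometric peak `T_max Ca0^2 / (Ca0^2 + ECa50(0)^2)` depends on the lengths
only through `SLD = Lr - L0`, and `DOC = t0 + t_r(Lr)` depends only on
`Lr`. The 13-scenario design (`build_scenario_table()`) probes exactly this
factorization: S0 varies `Lr` (SLD and DOC both move), S1 varies `L0` (SLD
moves, DOC fixed), S2 co-varies both at fixed SLD (only DOC moves).

## Analytics conventions

* **Metrics.** `SV = EDV - ESV`, `LVEF = 100 SV / EDV`, `CO = SV * HR/1000`
  with `HR = 60` (a 1-s cycle). Full precision internally.
* **Report formatting.** `metric_report()` displays LVEF and CO at 3
  decimals and computes percent changes *from the displayed values*,
  rounding half away from zero at 2 decimals. This mirrors how clinical
  tables are assembled (derived cells computed from the printed columns);
  with full-precision inputs the two conventions differ only in the last
  printed digit of a few CO cells.
* **Sensitivity.** Slopes are ordinary least squares (`stats::lm`) of a
  metric on the series' own parameter; the constant-SLD series is
  regressed on `Lr` along its diagonal path. Normalized sensitivity is
  `S* = (p_base / Y_base) * slope` with baselines from the control
  scenario. For a zero-variance response the slope, `S*` and `R^2` are all
  defined as 0 (never `NaN`). Piecewise segments are the four three-point
  fits flanking the baseline.
* **Deviation scores.** Range-type: distance outside `[L, U]` normalized by
  the range width; strain-type: `max(0, |x - mu|/sigma - 1)`. Both are
  invariant under affine re-uniting of a metric together with its bounds.
  Totals are sums over metrics; ranking is descending with lexicographic
  tie-break on scenario id. Reference means/SDs for regional strain are
  user-supplied (the literature values are not published numerically);
  the packaged tests use synthetic references.

## The 0D closed-loop surrogate

The organ level is explored with a deliberately reduced model - a
thick-walled spherical LV driven by the two constitutive laws, a passive
elastance atrium, ideal-diode valves, and arterial/venous compliances closed
through a peripheral resistance. Its purpose is directional: to show which
sign patterns of the scenario study follow from the constitutive laws alone,
not to reproduce finite-element volumes.

Design choices:

* **Geometry.** Midwall stretch `lambda = r_mid / r_mid,ref` with radii from
  the cavity and wall volumes; `P = 2 sigma log(r_out/r_in)` (thick-sphere
  Laplace). The wall tangential stress is the active fiber stress plus the
  mean in-plane passive stress of the equibiaxial state. Below the unloaded
  volume the isotropic term is compressive, providing diastolic suction
  (elastic recoil).
* **Integration.** Fixed-step explicit updates at `dt = 1e-4` s. The flow
  updates are antisymmetric between compartments, so total blood volume is
  conserved to round-off; the acceptance requirement is conservation, not a
  particular integrator, and the diode switching makes a fixed-step scheme
  the simplest robust choice.
* **Protocol.** A 0.3-s passive preload fill, then 1-s cycles with the
  twitch triggered at each cycle onset; EDV is the volume at beat onset and
  ESV the cycle minimum. Five cycles suffice for ~0.1% cycle-to-cycle EDV
  periodicity at baseline.
* **Calibration.** Wall/reference volumes, compliances and resistances were
  tuned once so the baseline scenario lands inside the normal ranges of all
  five cardiac-function metrics, then frozen in the packaged configuration
  (`default_params()`). The study's absolute volumes are deliberately not
  fitting targets. The mitral resistance (0.025 mmHg s/mL) gives
  physiological trans-mitral flow rates at a 3-10 mmHg gradient, so filling
  occupies most of diastole.

What the surrogate reproduces: the full `Lr`-series sign pattern (EDV and
ESV decrease, SV/LVEF/CO increase with `Lr`, driven jointly by the
Frank-Starling gain and the DOC encroaching on the filling window), exact
volume conservation, baseline periodicity, and a below-baseline EDV for the
short-`L0` scenario.

What it does not reproduce - a known structural limitation: the severe
short-`L0` collapse (the large SV and EDV reductions of the S11/S21-type
scenarios). In this law, lowering `L0` raises force at every length and
leaves the relaxation clock unchanged at equal lengths, so a single-cavity
ventricle with lower `L0` ejects deeper and refills at least as fast at any
matched atrial and arterial pressures; its single-beat transfer is never
below baseline's, and a closed loop therefore equilibrates at an equal or
higher stroke volume. The collapse seen in three-dimensional models arises
from a positive feedback unavailable to a fixed-geometry sphere: progressive
regional distortion that degrades diastolic compliance over successive
cycles. In the 0D setting the corresponding feedback is negative (less
filling shortens the onset length, which shortens relaxation and lengthens
the next filling window). Passing the surrogate tests therefore supports the
inotropic (`Lr`) axis and the bookkeeping of the loop, and explicitly does
not validate the diastolic-dysfunction phenotype.

## Synthetic data and recovery

The generators emulate the statistical structure the analytics assume:
scenario metric tables with linear parameter dependence plus Gaussian noise
(`synth_metric_table()`), noisy isometric peak-stress measurements truncated
at zero (`synth_twitch_measurements()`), and regional strain records with
scenario shifts around reference means (`synth_aps_records()`). Gaussian
noise is used throughout because no noise model is published; every
generator takes an explicit integer seed and has no hidden state, so fixed
seeds give byte-identical outputs. `recover_sld()` inverts the closed-form
peak for the length difference; the estimator is exact on noiseless input
and its error shrinks with the number of replicates. Passing recovery tests
shows the analysis pipeline is consistent with its own generative model -
it says nothing about real measurement noise, which is neither Gaussian nor
homoscedastic in force measurements.

## Problem sizes and runtimes

The test suite runs the full 13-scenario tissue sweep, the verification
grids, 200-replicate Monte-Carlo recovery, and short (2-5 cycle) surrogate
runs at `dt = 2e-4` s; the acceptance script and the organ-level acceptance
test run the complete 13 x 5-cycle protocol at `dt = 1e-4` s. These sizes
were chosen to keep every stage's sampling error at least an order of
magnitude below the tolerances being asserted.

## Known limitations

* The surrogate's circulation is an independent reduced design; any
  numerical claim about its pressures or volumes is internal to this
  package.
* Regional strain extraction from 3D fields, shear deformation modes,
  viscoelasticity, cross-bridge kinetics and calcium transient dynamics are
  out of scope.
* The `Ca0` / `Ca0_max` distinction in the active law is untestable with
  the default parameters (both 4.35) and is preserved as printed.
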