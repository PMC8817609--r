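---
title: "A reduced-order CT-derived wave-free ratio: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order CT-derived wave-free ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiFR)
```

## The physiological problem

The instantaneous wave-free ratio (iFR) grades a coronary stenosis by the
ratio of mean distal pressure to mean aortic pressure, Pd/Pa, during the
diastolic *wave-free period* — the part of diastole in which microvascular
resistance is low and stable — measured at rest with a pressure wire.
Lesions with iFR ≤ 0.89 are treated as hemodynamically significant.
Fractional flow reserve (FFR) is the analogous ratio under drug-induced
maximal hyperemia, with a 0.80 cutoff. A simulation-based, CT-derived iFR
estimates the same ratio from anatomy alone: reconstruct the coronary
lumen, impose resting boundary conditions, solve a steady flow problem,
and read Pd/Pa at the position where the pressure sensor would sit.
Because the index is resting, no conversion of boundary conditions from
baseline to hyperemia is required — the main modeling liability of
CT-derived FFR.

`ctiFR` implements that pipeline at desk scale, together with the
statistical battery used to evaluate such an index against invasive
references, and a synthetic cohort generator so the entire evaluation runs
with no external data.

## The flow model

**Geometry.** A vessel is a centerline tree: segments of ordered 3D points
with lumen radii (mm), one inlet, one outlet per leaf. Trees are
resampled to a uniform arclength step (default 0.5 mm, of the order of a
CT voxel) before solving; interfaces stay in clinical units (mm, mmHg,
mL/min) and the solver converts to SI internally.

**Boundary conditions.** The inlet pressure is the patient's diastolic
aortic pressure (1 mmHg = 133.322 Pa) — the steady stand-in for the
wave-free window, during which aortic pressure is near its diastolic
value. Resting inlet flow follows an allometric relation between the
myocardial mass `m` subtended by the vessel and flow,

\[ Q = c\,m^{\alpha}, \qquad c = 3.41\ \mathrm{mL\,min^{-1}\,g^{-\alpha}},\ \alpha = 0.75, \]

a ¾-power scaling calibrated so that a 300 g heart receives ≈246 mL/min
of total resting coronary flow. These coefficients are package
conventions, not measured quantities, and both are configurable. Outlet
flows divide by Murray's law, \(Q_i \propto d_i^{\gamma}\) with γ = 3,
using each outlet's diameter averaged over its distal 3 mm (averaging
damps discretization noise; no measurement convention is standard here).
Internal segment flows are the sums of their downstream outlet flows, so
conservation at junctions is exact by construction. Hyperemic mode
multiplies the inlet flow by a factor h (default 3, the typical
adenosine response) and is used only for the FFR surrogate.

**Pressure solve.** Along the resampled centerline the pressure drops, per
step of length `ds` with end areas \(A_{in}, A_{out}\):

\[ \Delta P = \underbrace{\frac{8\pi\mu Q\, ds}{\bar A^2}}_{\text{viscous}}
 + \underbrace{K_e \frac{\rho}{2} Q^2 \Big(\frac{1}{A_{in}} - \frac{1}{A_{out}}\Big)^2 \; [A_{out} > A_{in}]}_{\text{post-stenotic expansion}} \]

with \(\bar A = (A_{in}+A_{out})/2\), blood density ρ = 1056 kg/m³ and
viscosity μ = 0.0035 Pa·s (incompressible Newtonian blood, steady flow,
rigid wall, no slip). The viscous term is the Poiseuille law, exact for a
uniform tube at any step size; the expansion term is a Young–Tsai-type
separation loss active only where the lumen widens, with \(K_e = 1\) by
default. Children inherit the parent's terminal pressure at junctions.
The ratio field \(R = P/P_a\) equals 1 at the inlet and is non-increasing
along every root-to-leaf path; the computed index is R at the virtual
sensor, 30 mm (≈3 cm of wire) downstream of the lesion's minimal-lumen
point by arclength, clamped to the vessel end, following the
largest-radius child through bifurcations.

This 1D formulation deliberately replaces a 3D finite-volume Navier–
Stokes solve. It preserves every testable contract of the pipeline — the
boundary-condition scheme, the rheology, the index definition and cutoff,
monotonicity in severity and in flow — at a cost of milliseconds per
vessel, and the solver sits behind a narrow interface
(`solve_pressure_field`) so a 3D solver could be swapped in without
touching the rest of the package.

### Numerical behavior

* The viscous step rule is exact for uniform tubes (tested to relative
  error < 1e-10 against closed-form Poiseuille flow at several steps).
* On the standard synthetic test vessel (LAD-like, DS 50% — close to the
  ~44% mean severity such study populations show), halving the step from
  0.5 to 0.25 mm moves the index by < 0.001. The quadrature error grows
  with severity: at DS 70% the same halving moves the index by ~0.005.
  The 0.5 mm default balances that error against run time.
* Resampling preserves the arclength of straight or tapered segments to
  1e-9 mm and is idempotent at a matching step. On curved centerlines,
  resampling onto a non-nested grid cuts corners, shortening a 120 mm
  vessel by ~1e-4 mm (relative ~1e-6) — irrelevant at solver accuracy.
* Flow reversal and collateral flow are unsupported; trees are strictly
  diverging. Negative prescribed flow is an error.

### When the prescribed flow cannot be sustained

Prescribing flow regardless of lesion severity is the scheme's structural
assumption, and it fails physically for severe stenoses: the computed
distal pressure reaches zero before the outlet. The solver raises a
degenerate-physics error naming the point. In reality flow through such a
lesion would be pressure-limited; within the cohort generator we record
these vessels at a floor index of 0.05 with a `collapsed` flag —
"unmeasurably low distal pressure", as a wire would read in a subtotal
occlusion. Under the default cohort (severity up to 90%, hyperemic
factor 3), roughly a fifth of vessels collapse in the hyperemic solve and
far fewer at rest; all of them are deep in the positive class, so
classification results are insensitive to the floor's exact value. The
floor exaggerates how low severe-lesion FFR values are (a real 85%
stenosis has FFR ≈ 0.3–0.5, not 0.05), which inflates the index-vs-FFR
Bland–Altman spread; comparisons involving the FFR surrogate should be
read qualitatively.

## The synthetic cohort

Each synthetic "patient" contributes one vessel (mirroring single-lesion
study designs): type drawn from LAD/LCX/RCA with weights 0.72/0.11/0.17,
LV mass ~ Normal(120, 20) g truncated above 50 g, diastolic Pa ~
Normal(80, 8) mmHg truncated above 40, and a single cosine-profile lesion
of severity DS ~ Uniform(30, 90)% (the usual angiographic inclusion
window), length 15–25 mm, centered at 35–55% of the vessel length.
Geometric defaults — LAD 120 mm long with 1.5 mm inlet radius, LCX
80 mm/1.35 mm, RCA 110 mm/1.6 mm, taper 0.002 mm/mm, two side branches at
a 0.6 daughter/parent radius ratio — are typical epicardial dimensions,
chosen once. The vessel's inlet flow uses the territory's share of LV
mass (LAD 0.50, LCX 0.25, RCA 0.25), since the tree models one vessel,
not the whole coronary circulation. Under these conditions the computed
index crosses 0.89 near DS ≈ 65%, and ~30–45% of vessels are positive —
the same prevalence regime as clinical iFR/FFR populations.

"Invasive" measurements are the computed indices plus independent
Gaussian noise, clipped to (0, 1]: iFR = index + ε₁ and FFR =
FFR-surrogate + ε₂. Published agreement between a CT-derived resting
index and invasive iFR is ~0.046 (SD of paired differences), which
calibrates the realistic noise scale; the package default is a smaller
σ = 0.02 so unit-test statistics are stable, and both are configurable.
The FFR surrogate is obtained from the hyperemic solve rather than an
affine map of the resting index, preserving the physiological distinction
between the two measurements.

Seeding: one master seed yields per-vessel child streams, so cohorts are
reproducible and their first k rows do not change when n grows.

What the generator does **not** emulate: real CCTA segmentation error
(blooming, motion), diffuse and serial disease, bifurcation lesions
(excluded by design), collateral supply, correlated measurement error
between iFR and FFR, and drift of the wave-free window itself. Passing
tests therefore demonstrate the internal consistency of the pipeline and
its statistics — not clinical accuracy on real patients.

## The evaluation battery

Positivity is cutoff-inclusive (≤ 0.89 for the computed index and
invasive iFR, ≤ 0.80 for FFR) everywhere: confusion tables, decision
curves, cohort labels. Design choices that were genuinely open:

* **Confidence intervals** are Clopper–Pearson exact binomial (via
  `binom.test`). Published tables of this kind often print CIs whose
  method is not identifiable; point estimates, not CIs, are the
  reproducible part. Display rounding is half-up to whole percent.
* **ROC orientation** is fixed as "lower index ⇒ positive" with score
  1 − index, stated in the output. The AUC is the Mann–Whitney statistic
  with ties counted ½; its CI and the paired comparison use DeLong
  placement-value (co)variances, cross-checked in the tests against both
  a brute-force enumeration and an independent implementation (pROC).
* **Correlation comparison** uses the independent-samples Fisher r-to-z
  test; for two correlations sharing a variable on the same subjects the
  dependent-sample Steiger variant is provided (`steiger_compare`) but is
  not the default, matching how such comparisons are usually reported.
* **Decision curves** evaluate the fixed-cutoff classifier:
  NB(pt) = TP/n − (FP/n)·pt/(1−pt) on a default grid pt = 0.01…0.99,
  against treat-all and treat-none.
* **DS% measurement** takes the reference diameter as the maximum within
  the 10 mm proximal to the minimal lumen (falling back to the segment
  start). No imaging standard defines this reference on CCTA; this rule
  is a convention of the package, and with the default taper it recovers
  an inserted lesion's nominal severity within 1 percentage point.

## Problem sizes

The shipped tests solve single vessels (~300 centerline points) in
milliseconds and use cohorts of 36–200 vessels; the noise-degradation
property averages 20 seeds of 40-vessel cohorts. The acceptance script
evaluates one 36-vessel cohort plus closed-form fixtures. These sizes
were chosen to match the scale of the study design the generator
emulates while keeping the full suite near a minute on a laptop core.

## Known limitations

1D losses underestimate 3D pressure drops for eccentric, tortuous or
serial lesions; the expansion term vanishes under grid refinement for
smooth profiles (it matters for abrupt area steps, not the cosine
lesions generated here), so the viscous integral carries nearly all of
the gradient. The prescribed-flow assumption removes autoregulation:
severe lesions collapse rather than flow-limit. The mass–flow
coefficients and territory shares are population conventions, not
patient-specific. None of the cohort-level statistics are predictions
about any clinical dataset; they characterize the pipeline itself.
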