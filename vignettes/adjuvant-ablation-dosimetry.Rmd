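---
title: "Methods: voxel dosimetry and simulated adjuvant RF ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel dosimetry and simulated adjuvant RF ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After yttrium-90 radioembolization, quantitative ⁹⁰Y PET/CT often shows
markedly non-uniform microsphere deposition inside a tumor: contiguous
under-dosed ("cold") sub-volumes larger than 2 cm can persist even when the
mean tumor dose looks adequate.  `ablate90` implements a computational
analysis of a hybrid strategy: use the post-treatment dose map to guide
percutaneous radiofrequency (RF) ablation of exactly those cold regions,
then quantify how the absorbed-dose metrics of the *remaining* (unablated)
tumor improve.  The pipeline is entirely in silico — each electrode
placement is simulated with a biophysical model, never applied to a
patient.

The package has six computational layers: voxel grids and NIfTI I/O;
local-deposition dosimetry; Arrhenius damage models; an electro-thermal
ablation simulator; plan validation and a greedy planner; and cohort-level
statistics, plus a synthetic phantom generator that makes every stage
testable without patient data.

## Dosimetry

The local deposition method (LDM) treats each voxel as absorbing the beta
energy emitted within it, so dose is proportional to the local activity
concentration:

$$ D~[\mathrm{Gy}] = C \cdot \frac{A~[\mathrm{GBq}]}{m~[\mathrm{kg}]},
\qquad C = 49.67~\mathrm{Gy\,kg/GBq}, $$

with voxel mass from the tissue density (1060 kg/m³ by default).  The
constant is the closed-form committed dose per unit ⁹⁰Y activity
concentration (mean beta energy 0.9267 MeV, half-life 64.05 h, complete
local absorption); all three numbers are configuration
(`ldm_constants()`), not hard-wired.

Dose metrics follow the conventions used for radioembolization response
prediction:

* **Dxx** — the minimum dose to xx% of the structure volume, computed as
  the dose at rank `ceiling(xx% * N)` of the voxel doses sorted
  descending.  No interpolation: this makes every value exactly
  reproducible by a brute-force sort, which the test suite exploits.
* **V100** — the percentage of voxels receiving *strictly more than*
  100 Gy.
* **DVH** — cumulative (≥ dose) histogram starting at 100% at 0 Gy.

Eligibility for adjuvant ablation is D70 < 100 Gy for resin microspheres
and D70 < 150 Gy for glass, both strict.

A useful exact property of the rank definition, verified as a test
invariant: removing only voxels whose dose is below every retained voxel's
dose can never decrease Davg, D50, D70, D90 or V100, and leaves Dmax
untouched whenever the hottest voxel is retained.  This is the mechanism
behind the uniformly non-negative metric changes the pipeline reports.

## Thermal damage model

Cell death and vascular coagulation both use first-order Arrhenius
kinetics,

$$ \Omega(t) = \int_0^t A\, e^{-E_a / (R\,T(\tau))}\, d\tau,
\qquad SF = e^{-\Omega}, $$

with cell-death parameters A = 2.984×10⁸⁰ s⁻¹, Eₐ = 5.06×10⁵ J/mol and
vascular parameters A = 1.98×10¹⁰⁶ s⁻¹, Eₐ = 6.67×10⁵ J/mol.  The ablation
(kill) boundary is Ω ≥ 6.9, i.e. a surviving fraction of 0.001 (99.9%
kill); the threshold comparison is inclusive.  The pre-exponential factors
overflow double precision, so every rate evaluation happens in log space
as `exp(log A − Eₐ/(R T))`.  Integrals use the trapezoid rule on the
solver's time samples; the closed form at constant temperature and
additivity over concatenated intervals are tested to 1e-9 and 1e-12
relative error.

Vascular damage feeds back on perfusion: the coagulated fraction
C_f = 1 − exp(−Ω_vascular) shuts capillary flow down linearly,
w_b = w_b,nc (1 − C_f).  This produces the well-known **oven effect**:
tissue with lower baseline perfusion (cirrhotic liver) develops a larger
thermal lesion because less heat is carried away, which the simulator
reproduces as a strict inequality in the test suite.

## RF ablation simulator

The model is a water-cooled 17-gauge (1.473 mm diameter) straight
electrode with a 30-mm active tip inside a liver block held at 37 °C on
its outer boundary.  Two coupled problems are solved on a uniform
Cartesian grid:

1. **Quasi-static potential.** ∇·(σ∇V) = 0 with V = 1 on the active tip
   and V = 0 on the block boundary (dispersive ground), solved matrix-free
   by Jacobi-preconditioned conjugate gradients on the 7-point
   finite-volume stencil (harmonic-mean face conductivities).  σ is
   constant per tissue preset and temperature-independent, so the field
   shape is computed once and only the applied voltage varies.
2. **Pennes bioheat equation.**
   ρc ∂T/∂t = ∇·(k∇T) + w_b c_b (T_a − T) + q, with the RF Joule source
   q = σ|∇V|².  Each step splits the operator: the perfusion + source
   term is relaxed *exactly* per voxel (so the perfusion-only closed form
   holds to machine precision), then conduction is advanced implicitly by
   dimensional-split tridiagonal sweeps (unconditionally stable).  The
   sweep order alternates x→y→z / z→y→x between steps, which cancels the
   first-order splitting asymmetry; a 90° rotation test about the
   electrode axis agrees to ≈0.03 °C.

**Sub-voxel electrode boundary.** A 0.74-mm-radius electrode is thinner
than any practical voxel, and naive rasterization makes its effective
radius depend on the grid spacing — kill volumes then fail to converge
under refinement.  Both solvers therefore use a ghost-value boundary
treatment: for every tissue voxel whose face neighbour is an electrode
voxel, the fraction θ of the grid step at which the true cylinder surface
is crossed is computed from the analytic geometry, and the link weight to
the Dirichlet value is scaled by 1/θ.  Only the diagonal and right-hand
side change, so the operators stay symmetric positive definite.  The same
θ enters the Joule power bookkeeping (the surface face dissipates over the
tissue gap θh and is attributed to the tissue voxel).  With this treatment
the 600-s kill volume changes by about 5% between 1 mm and 0.5 mm spacing,
versus ~36% without it.

**Feedback controller.** The applied voltage is modulated each step so the
hottest tissue node stays below the 105 °C cap: a multiplicative update
with a proportional term on the lead-predicted error (lead time 3 s
anticipates the heating trend and prevents overshoot) plus a small
corrective term on the instantaneous error (removes the steady offset the
lead term alone would leave).  The setpoint sits 1 °C under the cap; runs
abort with a diagnostic if the cap is ever exceeded by more than 0.5 °C.
All nodes start at 37 °C; the active tip is pinned at the coolant
temperature (25 °C default — the device is water-cooled but no coolant
temperature is standardized, so it is exposed as configuration).

**Numerical economies.** Arrhenius rates below 39 °C are under 10⁻⁴ s⁻¹
and contribute < 0.1 to Ω over a full 600-s run — three orders of
magnitude below the 6.9 threshold — so they are treated as zero, which
roughly halves the cost of large runs.  Tissue parameters come from three
literature presets (normal liver, cirrhotic liver, HCC); the convention
for patient cases is the HCC preset for hepatocellular carcinoma and
normal liver otherwise.  The electrically insulated shaft proximal to the
active tip is passive in this model (no source, no thermal pinning).

**Reference problem sizes.** The package's reference single-electrode
scenario is a 10 cm tissue block (boundary ≥ 3.5 cm from the lesion edge;
perfusion screens the far field, so a 20 cm block changes the kill volume
negligibly while octupling the cost).  Comparative-statics checks (cap,
oven effect, duration monotonicity) run at 1 mm spacing with a 0.5 s step;
the grid-convergence study compares 1 mm against 0.5 mm at a 1 s step.
Pipeline-level phantom studies use 2 mm simulation grids matched to the
2 mm dose grid — the rebinning step maps fine simulation voxels onto
coarse dose voxels by centre location, with a coarse voxel set when at
least half of its covering fine voxels are beyond the kill threshold (the
occupancy rule is exposed; 0.5 is the default).

## Planning

Cold regions are 6-connected components of tumor voxels under the
100 Gy isodose whose minimum bounding-box edge is at least 20 mm
(operationalizing the "> 2 cm" visibility criterion; the edge rule is
configurable).  `validate_plan()` checks each predicted zone for: overlap
with spare organs (hard violation), a minimum 1 cm surface-to-surface
distance to gastrointestinal tissue (hard), the fraction of the zone
outside the tumor, and the fraction over the ≥ 100 Gy isodose (a soft
warning — ablating well-treated tumor is wasteful, not unsafe).
Distances are minimum Euclidean distances between surface voxel centres.

`auto_plan()` is explicitly a convenience heuristic, not a reproduction of
physician placement: greedily, up to four sites, it takes the largest
unserved cold region, points the electrode through its centroid along the
candidate straight path whose predicted zone incurs the fewest violations,
and keeps the longest duration (≤ 600 s) that validates.  It is
deterministic; ties break by candidate order.  The electrode is positioned
with its active-tip midpoint at the region centroid, since the lesion
grows around the active segment's middle — plans can always be supplied
manually as JSON instead, mirroring a physician-driven workflow.

## Synthetic phantoms

`make_phantom()` builds what the analysis assumes real cases look like: a
lumpy ellipsoid tumor (volume calibrated to the request within 5%), a
multiplicative lognormal uptake texture (exponentiated Gaussian random
field, 8 mm correlation length, log-SD 0.8) weighted toward the rim,
spherical cold regions (default 25 mm diameter at 15% relative uptake)
embedded fully inside the tumor via exact ball-erosion of the mask, a
liver background ellipsoid holding the activity not assigned to tumor, and
organ masks (a gastrointestinal tube, gallbladder ellipsoid, capsule
shell) for constraint exercises.  The map is renormalized so the voxel sum
equals the infused activity exactly.

Two generator choices deserve justification:

* **The tumor/liver activity split is derived from a target mean tumor
  dose** (sampled within the 67.3–210.2 Gy band of observed pre-ablation
  means, default cohort range 80–180 Gy) rather than fixed, because
  infused-activity-to-volume ratios in real cohorts vary by an order of
  magnitude and no single split keeps the mean dose realistic across the
  42.5–374.6 cm³ volume range.
* **Eligibility calibration** (`calibrate_to_eligibility()`) bisects the
  cold-uptake fraction downward until D70 crosses its device threshold.
  This only works when enough of the tumor volume is cold or in the lower
  texture tail; with the default texture the generated cases are already
  eligible almost surely, and the bisection exists for edge cases.  An
  infeasible case errors with diagnostics rather than silently passing.

What the phantoms deliberately do **not** model: PET acquisition physics
(noise, point-spread, reconstruction artifacts), respiratory motion, and
contouring uncertainty.  Tests passing on phantoms therefore demonstrate
the correctness of the computational chain under the stated statistical
structure, not robustness to scanner effects.

## Statistics

The cohort battery mirrors the analysis conventions of the clinical
literature: Kolmogorov–Smirnov normality screening (with the Lilliefors
correction, since parameters are estimated from the sample — the
uncorrected variant is available for comparison), two-sided paired t tests
on pre/post metrics, tie-corrected (mid-rank) Spearman correlation with a
t-approximation p-value (exact permutation available for n ≤ 10), and
simple linear regression tested against the constant model with
F = (n−2)R²/(1−R²).  Regression follows only correlations with
|ρ| > 0.5 (strict).  Significance is α = 0.05 throughout and no
multiple-testing correction is applied, matching the analysis the package
reproduces.

## Known limitations

* Constant electrothermal properties: no temperature dependence of σ or
  k, no vaporization or impedance roll-off, so very long or high-power
  ablations are outside the model's validity.
* Single straight monopolar electrode; no expandable or bipolar devices;
  ground is the whole block boundary.
* The planner is a heuristic; per-patient site counts or durations of any
  specific clinical cohort are not expected to be reproduced.
* Percentage tumor-volume change is reported as 100·(pre − post)/post —
  the convention under which the bundled per-tumor example table
  reproduces cell-for-cell; summary statistics printed elsewhere for that
  cohort do not recompute from its table under any simple convention and
  are not used as references.

## A minimal end-to-end example

```{r example}
library(ablate90)

case <- calibrate_to_eligibility(make_phantom(phantom_spec(
  seed = 7, grid = voxel_grid(c(96, 96, 96), 2),
  tumor_volume = 120, infused_activity = 1.3)))

cfg <- pipeline_config(
  sim = simulation_config(domain_size = c(80, 80, 80),
                          grid_spacing = 2, time_step = 1))
res <- run_case(case, cfg)
print(res)

tab <- cohort_table(list(res))
cohort_summary(tab)
```
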