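# ablate90

Voxel dosimetry and simulated adjuvant thermal ablation for yttrium-90
radioembolization.

## The problem

Microsphere deposition after ⁹⁰Y radioembolization is often strikingly
non-uniform: quantitative post-treatment ⁹⁰Y PET/CT can reveal contiguous
under-dosed tumor sub-volumes larger than 2 cm even when the mean tumor
dose looks adequate, and under-dosed tumor predicts poor response.
`ablate90` is a research toolkit for evaluating, entirely in silico, a
hybrid strategy: use the post-treatment dose map to guide percutaneous
radiofrequency (RF) ablation of exactly those cold regions, and quantify
the improvement in the absorbed-dose metrics of the remaining (unablated)
tumor.  It is aimed at medical physicists and interventional-radiology
researchers studying multimodality liver-directed therapy.

## What it computes

* **Dosimetry** — local-deposition-method dose maps
  (`dose = 49.67 Gy·kg/GBq × local activity concentration`), cumulative
  dose–volume histograms, and the metrics Davg, Dmax, D50/D70/D90
  (minimum dose to xx% of the volume, descending-rank convention) and
  V100 (% of volume above 100 Gy), plus the device-specific eligibility
  rule D70 < 100 Gy (resin) / < 150 Gy (glass).
* **RF ablation simulation** — the Pennes bioheat equation
  `ρc ∂T/∂t = ∇·(k∇T) + w_b c_b (T_a − T) + σ|∇V|²` coupled to a
  quasi-static potential solve for a water-cooled 17-gauge electrode with
  a 30-mm active tip, a feedback controller holding the hottest tissue
  node below 105 °C, and first-order Arrhenius kinetics
  `Ω = ∫A e^(−Ea/RT) dt` for both cell death (kill boundary Ω ≥ 6.9,
  99.9% kill) and vascular coagulation, which feeds back on perfusion as
  `w_b = w_b,nc (1 − C_f)` and reproduces the cirrhotic-liver "oven
  effect".
* **Planning** — detection of cold regions (>2 cm connected components
  under the 100 Gy isodose), safety validation of electrode plans
  (1 cm gastrointestinal margin, organ sparing), and a deterministic
  greedy auto-planner; plans are plain JSON.
* **Pipeline and statistics** — per-tumor subtraction of predicted
  ablation zones from the tumor mask, recomputation of all metrics on the
  unablated remainder from the same dose map, cohort tables, and the
  statistical battery (Lilliefors/KS normality, paired t, tie-corrected
  Spearman with an |ρ| > 0.5 regression gate, F test vs the constant
  model).
* **Synthetic phantoms** — seeded generators for realistic
  post-radioembolization cases (lognormal uptake texture, embedded cold
  spheres, liver background, organ masks), so the entire chain is testable
  without patient data.

Volumes are read and written as NIfTI-1 (`RNifti`); all fields live on
axis-aligned voxel grids.

## Worked example

One synthetic tumor, end to end:

```r
library(ablate90)

case <- calibrate_to_eligibility(make_phantom(phantom_spec(
  seed = 7, grid = voxel_grid(c(96, 96, 96), 2),
  tumor_volume = 120, infused_activity = 1.3)))
case
#> <tumor_case> 'phantom-7': resin device, tumor 121.2 cm^3, activity 1.30 GBq, tissue preset 'hcc'

dose_metrics(ldm_dose(case$activity_map), case$tumor_mask)
#> <dose_metrics> Davg 130.0 Gy | Dmax 1439.1 | D50 84.4 | D70 51.8 | D90 24.9 Gy | V100 43.3% (15156 voxels)

cfg <- pipeline_config(
  sim = simulation_config(domain_size = c(80, 80, 80),
                          grid_spacing = 2, time_step = 1))
run_case(case, cfg)
#> <case_result> 'phantom-7': 1 site(s); tumor 121.2 -> 86.6 cm^3 (40.1% change); dDavg 14.0 Gy, dV100 4.1 pp
```

Read: the tumor is eligible (D70 = 51.8 Gy < 100), carries one >2 cm cold
region, and a single simulated 600-s electrode placement through that
region removes 34.7 cm³ of (mostly under-dosed) tumor; the unablated
remainder's mean dose rises by 14.0 Gy and its V100 by 4.1 percentage
points — the dose profile of the tissue still treated only by
radioembolization improves because the worst-treated tissue is now ablated.

A bundled 15-tumor example cohort table (`example_cohort()`) exercises the
cohort conventions: `cohort_summary()` on it reports 33 total simulations
and a mean pre/post volume difference of 18.9 cm³, and
`pct_volume_change()` (convention `100 (pre − post) / post`) reproduces
its printed percentage column cell for cell.

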