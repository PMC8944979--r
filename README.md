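# condylometry

Quantifies the volume of the mandibular condylar **head** from CBCT-like
voxel data and relates it to sagittal and vertical skeletal patterns, the
way a 3D cephalometric study would — but validated end to end on synthetic
phantoms and simulated cohorts with known ground truth.

The package is aimed at researchers in dental/maxillofacial imaging who
need a reproducible, testable implementation of this measurement chain:

1. **Geometry** — voxel volumes (NIfTI-1, or a raw+JSON dialect) in
   Hounsfield units with a RAS/mm affine, plus named cephalometric
   landmarks (CSV/JSON) in the same world frame.
2. **Planes** — the Frankfurt horizontal fitted to the four porion/orbital
   landmarks by total least squares, and per-side cut planes through the
   pterygoid fovea parallel to it (the anatomical head/neck boundary),
   oriented head-side positive.
3. **Segmentation** — bone threshold in the closed window [226, 3071] HU,
   26-connected component around the condylion seed, clip at the cut
   plane; volume = voxel count × voxel volume (0.49/0.49/0.5 mm default
   spacing).
4. **Cephalometrics & classification** — signed ANB, intermaxillary
   divergence (folded to [0°, 90°]), total gonial angle (unfolded); closed
   central intervals 2 ± 2°, 41 ± 1°, 120 ± 5° define skeletal class
   I/II/III, hypo/normo/hyperdivergence, and
   horizontal/normal/post-rotation growth.
5. **Two-level statistics** — both condyles of a subject are correlated,
   so effects are estimated with a random-intercept model
   `y_ij = x_ij'β + b_i + ε_ij`, `b_i ~ N(0, τ²)`, `ε_ij ~ N(0, σ²)`,
   fitted by REML (profiled, one-dimensional optimization on log τ²/σ²)
   with Wald 95% CIs; crude, sex/age-adjusted and sex-stratified analyses;
   ICC(A,1) rater reliability with F-based CIs; exact two-sample power via
   the noncentral t distribution.
6. **Synthetic data** — condyle phantoms (ellipsoidal head + cylindrical
   neck) whose head volume above the cut has the closed form
   `π·a·b·(2c/3 − h + h³/(3c²))`, and cohort simulation with the
   two-condyles-per-subject variance structure, a sex effect, and negative
   vertical-pattern slopes.

## Worked example

```r
library(condylometry)

## a condyle phantom with known analytic head volume, segmented through
## the full landmark-driven chain
ph  <- make_phantom(phantom_spec(a = 7, b = 7, c = 9, cut_height_mm = -4.5))
seg <- segment_condylar_head(ph$volume, ph$landmarks, side = "R")
seg
#> <condyle_segmentation> side R: 12967 voxels, 1556.7 mm^3 (HU 226-3071)
#>   cut plane p0 (0.00, 4.00, -4.50), n (0.000, 0.000, 1.000)
ph$truth$head_volume_mm3
#> [1] 1558.623     # analytic cap volume; voxel estimate is -0.12% off

## a simulated 73-subject cohort (49 F / 24 M, two condyles each) and the
## crude vertical-pattern regression
cohort <- simulate_cohort(cohort_spec(seed = 20260927))
fit_random_intercept(cohort, covariates = "gonial_deg")
#> Random-intercept linear model (REML): volume_mm3 ~ gonial_deg
#>   146 condyles in 73 subjects; tau^2 = 4.086e+04, sigma^2 = 1.715e+04
#>         term estimate      se    ci_lo    ci_hi p_value
#>  (Intercept) 2632.051 459.461 1731.525 3532.578 1.0e-08
#>   gonial_deg  -15.922   3.784  -23.339   -8.505 2.6e-05

## the protocol-phase power calculation: 850 vs 650 mm^3, SD 250,
## 20 males / 40 females, two-sided alpha 0.05
two_sample_power_percent(850, 650, sd = 250, n1 = 20, n2 = 40)
#> [1] 82
```

The volume estimate sits within a fraction of a percent of the analytic
truth; the fitted slope of −15.9 mm³ per degree of gonial angle recovers
the generator's −16.5 mm³/° within its Wald interval; and the power
computation reproduces the 82% figure from the emulated design.

## Analysis workflow

Numbered drivers under `analysis/` run the study as a pipeline and write
their tables to `results/`:

| script | what it does |
|---|---|
| `01_phantom_volumetry.R` | voxel vs analytic volumes across cut heights and spacings |
| `02_cephalometrics.R` | angle construction → measurement → classification grid |
| `03_cohort_analysis.R` | simulated cohort, group summaries, regression battery |
| `04_reliability_power.R` | 3 raters × 3 subjects × 3 sessions ICCs; power |
| `05_end_to_end_study.R` | full `run_study()` over phantom subjects written to disk |

`Rscript analysis/00_run_all.R` runs everything in order.

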