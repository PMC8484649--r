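# cortexdyn

Quantitative analysis of asymmetric actomyosin cortex dynamics in early
embryos — built for the classic *C. elegans* setting where a mother cell
(EMS) divides into daughters (E and MS) with visibly different cortical
F-actin and myosin, and the question is whether those molecular differences
translate into differences in cortical *mechanics*, *positioning* and
*shape*.

The package is aimed at researchers who have annotation-level measurements
(marker tracks from laser-ablation movies, cortical intensity tables,
lineaged nuclei positions, segmented label volumes) and want a tested,
reproducible statistical pipeline from those tables to inference. It is
tidyverse-native: data frames in, tibbles out, fit objects with
`tidy()`/`glance()`/`autoplot()` methods.

## What it computes

**Recoil mechanics.** After a line ablation of the cortex, marker velocities
orthogonal to the cut decay as

> v⊥(t) = v⊥,0 · exp(−t/τ)

with v⊥,0 proportional to cortical tension and τ (= friction/stiffness)
inversely related to stiffness. The pipeline goes: manual-PIV forward
differences (`track_velocities`) → optional cortical-flow correction
(`mean_flow`, `correct_flow`) → outward-positive orthogonal projection
within a 2.5 µm band (`orthogonal_samples`) → profile-least-squares fit
(`fit_recoil`) → experiment-weighted bootstrap CIs (`bootstrap_recoil`,
n = 1000) and weighted-bootstrap permutation contrasts between cells
(`permutation_contrast`). Binned flow fields (`flow_field`) and cortical
feature lifetimes with one-way ANOVA (`lifetime_anova`) round out the
kinematics.

**Intensity correction cascade.** Cortical fluorescence is corrected in a
fixed order — background subtraction, per-embryo scaling factors
s_e = Ī\*/Ī\*_e, then an additive model f(t, z) with a linear bleaching term
and a smoothing spline in log plane depth — and normalised to I⁺ with mean
≈ 1 (`subtract_background`, `embryo_scaling`, `fit_confounders`, or
`correct_intensity` for the whole cascade). Per-cell least-square means are
estimated by GLS with AR(1) time correlation (`cell_means_ar1`,
`contrast_cells`), plus quadratic time trends (`quadratic_time_fit`),
tensor-spline spatiotemporal surfaces around the cytokinetic furrow
(`spatiotemporal_surface`), natural-spline interface profiles
(`interface_profile`) and a mixed two-way ANOVA for interface asymmetry
(`interface_asymmetry_test`).

**Positioning.** Eight-cell-stage time alignment (`time_align`),
similarity Procrustes without reflections (`procrustes`), a Generalized
Procrustes consensus embryo (`gpa_reference`), per-cell per-axis
displacements (`axis_displacements`) and Wilcoxon rank-sum group tests
(`displacement_test`, `displacement_screen`).

**Shape.** Label-volume morphometrics: volume (`cell_volume`), Wadell
sphericity Ψ = π^⅓(6V)^⅔/A with a gradient-based (coarea) surface-area
estimator (`sphericity`), division volume ratios (`volume_ratio`), and the
longitudinal mixed model `sphericity ~ 1 + time + category + (1 | embryo)`
with a likelihood-ratio test for the treatment effect (`sphericity_model`).

**Synthetic data.** Every input has a generator with stored ground truth
(`gen_recoil`, `gen_intensity`, `gen_embryos`, `gen_embryo_series`,
`gen_solid`, `gen_lifetimes`, `gen_surface_samples`, `gen_sphericity`), so
the full pipeline runs and is validated end to end without any microscopy
data. `run_pipeline()` drives everything from a YAML config with
deterministic, seed-derived outputs.

## Worked example

Simulated ablations of an E cell (4 experiments) and an MS cell
(7 experiments), E generated with twice the initial recoil velocity:

```r
library(cortexdyn)

ex_e  <- lapply(1:4, function(j) gen_recoil(v0_true = 1.5, tau_true = 1.5,
  seed = 100 + j, experiment_id = paste0("E", j), cell = "E"))
ex_ms <- lapply(1:7, function(j) gen_recoil(v0_true = 0.75, tau_true = 2.5,
  seed = 200 + j, experiment_id = paste0("MS", j), cell = "MS"))

bootstrap_recoil(ex_e, n_boot = 1000, seed = 1)
#> <recoil_fit> v0 = 1.497 um/s, tau = 1.492 s (n = 480)
#>   95% CI: v0 [1.472, 1.522], tau [1.458, 1.528]
bootstrap_recoil(ex_ms, n_boot = 1000, seed = 2)
#> <recoil_fit> v0 = 0.7518 um/s, tau = 2.479 s (n = 840)
#>   95% CI: v0 [0.7333, 0.7679], tau [2.399, 2.572]

permutation_contrast(ex_e, ex_ms, parameter = "v0", n_perm = 1000, seed = 3)
#> <recoil_contrast> v0: E (1.497) vs MS (0.7518), |diff| = 0.7454, p = 0.000999 (1000 permutations)
```

Reading: the fitted initial outward velocities recover the generating 2:1
tension ratio (1.497 vs 0.752 µm/s, ratio ≈ 2.0) with non-overlapping 95%
bootstrap intervals, and the weighted-bootstrap permutation test puts the
difference at p ≈ 0.001 — the E cortex is under roughly twice the tension
of MS in this simulation. The τ estimates (1.49 s vs 2.48 s) likewise
recover E's stiffer cortex.

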