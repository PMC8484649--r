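---
title: "Quantifying asymmetric cortical dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asymmetric cortical dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexdyn)
```

cortexdyn quantifies how the actomyosin cortex of early embryonic blastomeres
differs mechanically and molecularly between sister cells, using four
complementary read-outs: laser-ablation recoil mechanics, cortical
fluorescence levels, nuclei positioning, and cell-shape morphometrics. This
vignette explains the underlying models, the assumptions they make, the
tunable parameters, and the numerical choices — in the order the pipeline
runs them. Every stage can be exercised on synthetic data with known ground
truth; the final section spells out what those synthetic checks do and do not
establish about real microscopy data.

## 1. Recoil mechanics after laser ablation

Severing the cortex along a short line releases the in-plane tension it
carried. Treating the cortex as an active viscoelastic gel, the velocity of
cortical markers away from the cut decays exponentially:

$$ v_\perp(t) = v_{\perp,0}\, e^{-t/\tau}, $$

where the initial outward velocity $v_{\perp,0}$ (um/s) is proportional to
the tension across the cut, and the relaxation time $\tau$ (s) equals
friction over elastic stiffness. Only the ratio is identifiable: the package
never reports friction or stiffness separately. No resealing term is
included because fits use only the first seconds after the cut, before wound
repair dominates.

**From annotated tracks to velocity samples.** The input is manual-PIV style
marker tracks. `track_velocities()` takes forward finite differences between
consecutive annotated frames; each velocity is therefore an *average over a
frame interval*, timestamped at the interval midpoint, with the interval
endpoints retained. `orthogonal_samples()` projects velocities onto the
cut-line normal with an outward-positive sign convention on both sides of the
cut (a marker's side is its initial signed offset, or the first off-line
position if it starts exactly on the line). Markers further than
`band_halfwidth` (default 2.5 um) from the cut at their first frame are
excluded, and only samples with midpoint times in the closed window
`[0, fit_window]` (default 6 s) enter the fit.

**Flow correction.** When an experiment includes flow-role reference tracks
(markers away from the cut that report bulk cortical flow), the mean flow
vector per timestep is subtracted from every velocity before projection.
Timesteps without a flow sample inherit the nearest preceding mean. Because
projection is linear, correcting before or after projection is equivalent;
the test suite asserts this commutation.

**Fitting.** Given $\tau$, $v_{\perp,0}$ enters the model linearly, so
`fit_recoil()` profiles the (optionally weighted) residual sum of squares
over $\tau$ alone: a 48-point log-spaced grid over the admissible range
$[0.05, 60]$ s followed by one-dimensional polishing in the best bracket.
This is globally robust (no starting values to tune) and two orders of
magnitude faster than generic nonlinear least squares, which matters for the
bootstrap below. The lower $\tau$ bound guards against degenerate spikes when
recoil decays within a single frame. When samples carry interval endpoints,
the model fitted is the interval average
$v_{\perp,0}\,\tau\,(e^{-t_0/\tau}-e^{-t_1/\tau})/(t_1-t_0)$ — the exact
expectation of a finite-difference velocity under the decay model. Without
this, a decay with $\tau$ comparable to the frame interval would be
systematically misestimated (about 17% for $\tau = 0.5$ s at 1 fps);
with it, noiseless synthetic data are recovered to optimizer precision.
Pointwise samples (no interval columns) are fitted with the plain
exponential. If every projected velocity is non-positive, the fit returns
$v_{\perp,0} = 0$ with $\tau$ flagged unidentifiable.

**Weighted bootstrap.** Experiments contribute very different numbers of
samples, so `bootstrap_recoil()` resamples individual velocity samples with
probability $1/(E\,n_e)$ — $E$ experiments, $n_e$ samples in the sample's
experiment — so each *experiment* is sampled with equal probability
(n_boot = 1000 by default). Confidence intervals are 2.5/97.5 percentiles;
the point estimate is the weighted fit on all samples. Failed replicates are
redrawn, and more than 10% failures aborts. An alternative two-stage scheme
(resample experiments, then samples within) was considered and not used: the
per-sample weighting is the most direct reading of equal-probability
sampling per experiment, and the two schemes agree in the balanced designs
used here. One caveat the tests make visible: adjacent velocities on a track
share one frame of positional noise, so samples are not exchangeable in the
strict iid sense, and percentile intervals come out mildly conservative
(coverage at or just above the nominal 95% in the calibration study).

**Permutation contrasts.** `permutation_contrast()` tests a difference in
$v_{\perp,0}$ or $\tau$ between two cells. Each null replicate draws a
weighted bootstrap dataset from the pooled pair, shuffles the cell labels
within it, refits both groups and records the absolute parameter difference;
the p-value is the fraction of null replicates at least as extreme as the
observed difference. An add-one correction keeps p strictly positive
(`add_one = FALSE` recovers the plain proportion). A `resample = FALSE` mode
shuffles labels on the observed samples only — the classical permutation
test — which is what the exhaustive-enumeration oracle in the test suite
checks against, since the bootstrap-then-shuffle null is not literally the
permutation distribution. A more conservative experiment-level shuffle was
considered and rejected as the default because the sample-level shuffle is
the procedure the weighted-bootstrap construction defines; with very few
experiments per cell an experiment-level shuffle has almost no support.

**Flow fields and feature lifetimes.** `flow_field()` bins velocities on a
(position, time) grid and reports per-bin means with counts; empty bins are
flagged, never interpolated. `track_lifetimes()` defines a feature's
lifetime as last minus first annotation time plus one frame interval, and
`lifetime_anova()` compares region means by classical one-way ANOVA.

## 2. The intensity correction cascade

Cortical fluorescence comparisons between cells are confounded by embryo-to-
embryo brightness differences, photobleaching, and depth-dependent signal
loss across z-planes. The cascade removes them in a fixed order:

1. **Background subtraction** — the locally measured background is
   subtracted per record; negative differences are floored at zero and
   flagged (`subtract_background()`).
2. **Per-embryo scaling** — each embryo's records are multiplied by
   $s_e = \bar I^* / \bar I^*_e$ (grand mean over embryo mean), equalising
   embryo means (`embryo_scaling()`). The grand mean is taken over all
   records of all embryos; with equal record counts this preserves the grand
   mean exactly.
3. **Bleaching and depth** — an additive model $f(t, z)$ with a *linear*
   time effect (bleaching) and a smoothing spline in $\log z$ (depth) is
   fitted across all embryos by penalised regression (`mgcv::gam`), with
   smoothness chosen by generalised cross-validation and the spline basis
   capped at the number of distinct planes. Each observation is corrected
   and normalised as $I^+ = (I^{*} - f(t,z) + \bar I^{*})/\bar I^{*}$, so
   corrected values fluctuate around 1 (`fit_confounders()`). With a single
   plane or a single timepoint the corresponding term is dropped with a
   warning.

On data simulated with all confounders switched off the cascade is exactly
the identity ($I^+ \equiv 1$); the acceptance suite asserts this.

**Cell means under AR(1) errors.** Records within an (embryo, cell, plane)
series are strongly autocorrelated in time. `cell_means_ar1()` fits
$I^+ \sim \text{cell}$ by generalized least squares with a first-order
autoregressive correlation structure within each series (`nlme::gls` with
`corAR1`), a single common $\rho$ across series (a per-series $\rho$ added
little in simulation and is harder to estimate from short series). With only
the cell factor in the model, the coefficients are the least-square means;
their standard errors come from the GLS covariance. Degrees-of-freedom
corrections of the Satterthwaite type are approximated by normal-theory
intervals — a deliberate simplification, adequate at the series lengths
used here (tens of timepoints). `contrast_cells()` forms pairwise
differences with covariance-propagated standard errors;
`quadratic_time_fit()` fits per-cell quadratic time trends under the same
AR(1) structure, with a pointwise ±1 SE band from the coefficient
covariance (falling back to ordinary least squares when the AR(1) fit is
singular, e.g. on noise-free data).

**Spatiotemporal surface.** For heatmaps of intensity against (position
relative to the cytokinetic furrow, time relative to closure), samples are
standardized per embryo (mean 0, SD 1 — embryos with zero variance are
excluded) and pooled into a tensor-product spline surface
(`spatiotemporal_surface()`), evaluated on a grid with exported
iso-intensity contours. The signed furrow coordinate puts the anterior (MS)
side negative and posterior (E) side positive; the choice is arbitrary and
only affects plot orientation.

**Interface profiles and asymmetry.** `interface_profile()` fits a natural
cubic spline (df = 4 by default) to normalized intensity along a cell-cell
contact, exact for linear signal by construction.
`interface_asymmetry_test()` range-scales each embryo's contact values to
[0, 1], averages per embryo x side, and runs a two-way mixed ANOVA (side
within embryo, treatment between embryos) via `aov` with an
`Error(embryo/side)` stratum — the repeated-measures structure matching one
pair of sides per embryo.

## 3. Nuclei positioning

`time_align()` picks, per embryo, the last timepoint at which all four AB
granddaughters exist undivided — the end of the eight-cell stage — making
embryos comparable in developmental time. `procrustes()` then computes the
least-squares similarity superimposition (translation, proper rotation,
isotropic scale) of one snapshot onto another over shared cell names.
Reflections are explicitly excluded: embryo chirality is biologically
meaningful, and a mirrored embryo must *not* align perfectly. Scaling is
included by default (a rigid mode is available via `scale = FALSE`).

`gpa_reference()` builds a consensus embryo by Generalized Procrustes
Analysis: iterative alignment to the evolving mean shape, renormalised to
unit centroid size, until the mean changes by less than 1e-8 RMS (at most
100 iterations). Two presentation choices matter downstream and are options
rather than defaults hidden in code:

- the mean shape's coordinate frame is arbitrary, so anatomical axis labels
  (AP/DV/LR) are attached by rotating the reference onto an orientation
  template of known axes (`orient_to`);
- with `size = "mean"` the reference is rescaled to the mean centroid size
  of the input embryos, so displacements are in micrometres rather than
  unit-shape coordinates.

`axis_displacements()` aligns every embryo to the reference and reports
signed per-cell, per-axis displacements. Because the alignment itself uses
the displaced cell, part of any single-cell shift is absorbed into the
fitted translation/rotation/scale: displacements sum to approximately zero
across cells, and an injected shift of size $d$ reappears at roughly
$0.75\,d$–$0.8\,d$ on the shifted cell (the acceptance suite quantifies
this). `displacement_test()` compares per-embryo displacements of one cell
along one axis between groups with a two-sided Wilcoxon rank-sum test
(midranks under ties); per-embryo rather than pooled-over-timepoints values
are used, keeping embryos as the independent units. No multiple-testing
correction is applied by default — the screening helper
`displacement_screen()` offers Benjamini-Hochberg for exploratory scans.

## 4. Shape morphometrics

`cell_volume()` is voxel count times voxel volume. `sphericity()` implements
Wadell sphericity $\Psi = \pi^{1/3}(6V)^{2/3}/A \in (0, 1]$. The delicate
part is the surface area $A$ of a voxelised label: counting exposed voxel
faces overestimates $A$ by up to ~50% (a staircase never converges to the
smooth surface), which is unusable. Instead the binary mask receives one
Gaussian smoothing pass (SD 0.65 voxels, isotropic in physical units) and
$A$ is estimated by the coarea formula as the integral of the gradient
magnitude of the smoothed indicator — for a smoothed step across an
interface, that integral equals the interface area. The smoothing width
balances two opposite biases: too little smoothing leaves staircase
roughness (area overestimated on curved surfaces), too much rounds edges
away (area underestimated on facetted ones). At 0.65 voxels, calibration
against closed forms gives a discretised sphere within ~1% of $\Psi = 1$
and a cube within ~3% of $(\pi/6)^{1/3} \approx 0.806$; raw (pre-clip)
$\Psi$ stays below the isoperimetric bound plus 2% discretisation slack on
random ellipsoids. Values are clipped at 1, with the raw estimate kept as an
attribute.

`sphericity_model()` fits the longitudinal mixed model
`sphericity ~ 1 + time + category + (1 | embryo)` by REML (`lme4`), after a
model-simplification step that considers a per-embryo random time slope and
drops it unless a likelihood-ratio test supports it at the 0.05 level.
The treatment effect is tested by a likelihood-ratio chi-square between
maximum-likelihood refits with and without `category`. `volume_ratio()`
reports division asymmetry as min/sum.

## 5. What the synthetic generators emulate — and what they do not

Every pipeline input has a generator with a machine-readable `truth`
attribute, so recovery can be asserted, not eyeballed:

- `gen_recoil()` inverts the recoil model: marker displacement follows the
  closed-form integral $v_0\tau(1-e^{-t/\tau})$ outward on both sides of the
  cut, plus optional uniform flow and iid Gaussian positional jitter per
  frame (defaults: $v_0 = 1$ um/s, $\tau = 2$ s, 20 markers, 0.05 um noise,
  1 fps for 7 s — scales typical of cortical ablation recordings). Because
  velocities difference two noisy positions, their noise variance is
  $2\sigma^2/\Delta t^2$ and adjacent velocities of one track are negatively
  correlated; recovery tolerances respect this.
- `gen_intensity()` multiplies cell, embryo, linear-bleaching and
  depth-attenuation effects, adds a recorded background and AR(1) noise.
- `gen_embryos()` places a fixed two-rings-of-four reference layout of the
  eight blastomeres under random similarity transforms with per-nucleus
  jitter; treated embryos shift one named cell in reference coordinates
  before transforming. The layout is deliberately schematic — the
  positioning methods are geometry-agnostic, and no claim about real embryo
  geometry is made.
- `gen_solid()` rasterises analytic solids; `gen_lifetimes()` draws
  exponential or gamma lifetimes per cortical region;
  `gen_surface_samples()` samples a known smooth field with per-embryo gain
  and offset.

What passing the synthetic checks shows: the estimators are consistent with
their own model assumptions, the inference machinery is calibrated (CI
coverage, type-I error, false-flag rates at study-scale sample sizes of 4–7
ablation experiments per cell, 8 vs 10 embryos for positioning, 5 vs 7 for
sphericity), and the closed-form cases are hit to stated tolerances. What it
does not show: robustness to mis-specified noise (tracking errors in real
annotations are neither Gaussian nor independent of signal), to nonlinear
bleaching (the generator can be made mildly nonlinear for robustness
exploration, but the correction model is linear in time by design), to
segmentation artefacts in label volumes, or to genuinely non-similarity
deformations between embryos.

## 6. Numerical choices and problem sizes

Tolerances and defaults in one place: recoil $\tau$ bounds $[0.05, 60]$ s,
48-point profile grid, optimizer tolerance 1e-10; n_boot and n_perm default
to 1000 with an add-one p-value correction; GPA tolerance 1e-8, at most 100
iterations; sphericity smoothing 0.65 voxels with a minimum of 100 voxels
per label; natural-spline df 4; depth-spline basis capped at the number of
distinct planes. Determinism: every stochastic function takes a `seed` and
restores the caller's RNG state; `run_pipeline()` derives per-stage seeds
from a single base seed, making identical configurations byte-identical in
output. The calibration studies in the test-suite and acceptance script use
200 recovery replicates, 150–300 coverage datasets with 1000 bootstrap
replicates each, 300–500 null datasets for permutation calibration, and
60–100 replicates for the intensity and positioning power studies — sizes
at which the Monte-Carlo error of each rate is a percentage point or two,
commensurate with the acceptance bands they are compared against.

## 7. Known limitations

- The recoil model has no resealing term; fits on windows much longer than
  the default 6 s would be biased on real data.
- The permutation null (bootstrap-then-shuffle) is slightly conservative in
  small designs, and the bootstrap percentile intervals are mildly
  conservative under within-track noise correlation; both calibrations are
  quantified, not hidden.
- Least-square-mean intervals use normal theory, not Satterthwaite degrees
  of freedom; with very few embryos the intervals are somewhat anticonservative.
- Procrustes absorption means single-cell displacement estimates are biased
  toward zero by a geometry-dependent factor; group comparisons are
  unaffected (both groups are aligned identically), but absolute
  displacement magnitudes should be read with this in mind.
- The sphericity surface-area estimator is calibrated for compact,
  moderately smooth cells resolved by at least ~10 voxels across; thin
  protrusions below the smoothing scale are smoothed away.
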