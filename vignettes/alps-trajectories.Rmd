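---
title: "Glymphatic trajectories: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glymphatic trajectories: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpstraj)
```

## What the package models

Two imaging proxies sit at the center of this package. The **DTI-ALPS
index** exploits the geometry at the body of the lateral ventricle: the
medullary veins (and their perivascular spaces) run left–right (x),
perpendicular both to the projection fibers (inferior–superior, z) and to
the association fibers (anterior–posterior, y). Inside a projection-fiber
voxel, diffusivity along x is *across* the axons, so any excess of
`Dxx` over the other cross-fiber diffusivity (`Dyy`) must come from the
perivascular compartment; the same holds for association fibers with
`Dzz` as the cross-fiber reference. The index

$$\mathrm{ALPS} = \frac{(D_{x,\mathrm{proj}} + D_{x,\mathrm{assoc}})/2}
                       {(D_{y,\mathrm{proj}} + D_{z,\mathrm{assoc}})/2}$$

is therefore 1 under no preferential perivascular diffusion and rises
with glymphatic clearance. Directional diffusivities are read from the
diagonal of the fitted tensor in the template frame — the standard ALPS
practice — not from eigenvector projections, and the four (two per
hemisphere) 5-mm spherical ROIs are supplied as explicit voxel
coordinates; no automatic atlas placement is attempted.

The **brain-PAD** of a structure is `predicted age − chronological age`,
so a positive value means an older-appearing structure. The sign matters:
descriptions of the computation sometimes read chronological-minus-
predicted, but an accelerated-aging group can only show *positive* mean
PADs under predicted-minus-chronological, so that convention is used
throughout. Age prediction itself (deep-learning segmentation and
regression) is upstream of this package; predicted ages arrive as a
table.

The statistical battery then asks three questions: do the groups differ
in PAD (gated two-group tests), does ALPS decline along aging indices
(OLS trajectories), and do the groups share those trajectories
(slope-equality tests), with sex-controlled partial correlations linking
PAD to cognition and Benjamini–Hochberg FDR within each report table.

## Tensor fitting and scalar maps

`fit_tensor()` uses ordinary (unweighted) log-linear least squares on
`log S` against the b-matrix, the classical estimator: with a shared
design across voxels the normal equations are solved once for the whole
volume. The choice of *unweighted* LLS is deliberate — it is the simplest
estimator consistent with generic "DTI tensor fitting", it is exactly
unbiased in the noise-free limit used by the validation phantoms, and at
the phantom SNR (noise SD 15 on signals of 250–1000) the efficiency loss
against weighted LLS is negligible. Voxels with any nonpositive signal
cannot be log-transformed and are masked and counted, never imputed.

Negative eigenvalues are *flagged, not clamped*
(`tensor_eigen()$negative_eigenvalue`). Clamping would bias ALPS ratios
toward 1 in low-SNR voxels in a way that is invisible downstream;
reporting leaves the decision with the analyst.

Scalar maps follow the standard eigenvalue formulas (MD = mean, AD =
largest, RD = mean of the two smallest, FA via the normalized eigenvalue
dispersion), with FA defined as 0 at an all-zero voxel.

Voxel indices are **1-based** everywhere, matching R and every R
neuroimaging package; volumes are reoriented to RAS at load so that the
tensor's x component is left–right.

## ROI geometry

A voxel belongs to a spherical ROI when its center lies within
`diameter/2` of the center voxel's center in physical millimetres,
*inclusive* (with a 1e-12 slack against floating-point ties on exact-
radius shells). On a 1-mm grid the default 5-mm sphere holds 81 voxels.
Spheres are clipped at the grid boundary, and the center voxel is always
a member, so masks are never empty. Hemispheric indices are averaged by
default (`mode = "mean"`); since reports rarely state laterality
handling, the mode is explicit and logged, and a missing hemisphere
degrades to the available one with a message rather than an error.

## The synthetic phantom

`phantom_config()` builds a 32³, 1-mm volume with four disjoint fiber
boxes (projection/association × left/right) in an isotropic background
(0.7×10⁻³ mm²/s). Fiber tensors are diagonal with axial eigenvalue
1.4×10⁻³ and perpendicular eigenvalue 0.4×10⁻³ mm²/s — typical
white-matter values — and the subject's glymphatic level `g` enters as
`Dxx = g · λ⊥` in both fiber classes. This makes the analytic index equal
`g` exactly, strictly increasing in `g`, which gives every downstream
test a closed-form truth. Signals are forward-simulated on a
deterministic 60-direction b = 1000 s/mm² shell with three b = 0
references (golden-angle sphere spiral, so no seed is needed for the
scheme itself); noise is Gaussian on signals by default (SD 15, S0 =
1000; Rician optional). `predict_alps_se()` propagates that noise
analytically (delta method through the fit, the ROI means and the ratio),
and the pipeline estimate agrees with the analytic index to 1e-10 without
noise and within 3 predicted SEs with it.

What the phantom deliberately does **not** emulate: anatomy beyond the
four boxes, registration error, eddy/motion artifacts, partial-volume
mixing at region edges, or Rician bias at low SNR. Passing phantom tests
therefore validates the *computational chain*, not robustness to
acquisition pathology.

## The synthetic cohort

`cohort_config()` encodes the study conditions as defaults: 45 controls
and 100 HIV subjects, ages uniform on 20–70. Per-structure predicted ages
are `age + δ·1(HIV) + N(0, σ)` with δ = +3 years on the four affected
(operculum / inferior-frontal) structures and σ = 6.5 years — a scatter
chosen so that a +3-year offset at these group sizes yields group-test
t-statistics in the 2–3 range, the regime such cohort tables typically
show. The ALPS index follows

$$\mathrm{ALPS} = \alpha_g + \beta^{\mathrm{age}}_g(\mathrm{age}-45) +
  \beta^{\mathrm{PAD}}_g \cdot \mathrm{PAD}_{\mathrm{cpl}} + \varepsilon,
  \qquad \varepsilon \sim N(0, 0.12),$$

with control parameters α = 1.45, β^age = −0.04/decade, β^PAD = −0.04/yr
on the PAD of a designated *coupling structure* (default: left central
operculum), and a flat, lower HIV profile (α = 1.38, both slopes 0) —
magnitudes in the range reported for ALPS-vs-PAD trajectories in aging
cohorts. Driving ALPS through a single coupling structure keeps the
configured slope an exact estimand for the regression, at the cost of
realism (real per-structure PADs are mutually correlated, so real
trajectory tables show attenuated, correlated slopes across many
structures). Motor and abstract/executive T-scores lose 0.45 points per
PAD year (pooled PAD–motor correlations around −0.3); the other four
domains are pure N(50, 10) noise. Blood markers are drawn from
group-typical lognormal/normal distributions and are NA for controls.
Every draw is a pure function of `(config, seed)` via `withr::with_seed()`.

## Statistical choices

- **Gating** (`compare_groups()`): Shapiro–Wilk per group and Levene's
  test (Brown–Forsythe, `center = median`) at α = 0.05; *any* failure
  routes to Mann–Whitney. There is no Welch intermediate — the design is
  a strict either/or. Both groups constant at the same value returns
  statistic 0, p 1 by convention.
- **Mann–Whitney**: exact enumeration when `n1·n2 ≤ 400` and no ties,
  otherwise the tie-corrected normal approximation without continuity
  correction, matching the midrank U definition used as the test oracle.
- **Slope equality** (`compare_slopes()`): `t = (b₁−b₂)/√(SE₁²+SE₂²)`
  with `df = n₁+n₂−4` from two independent fits. This is close to, but
  not algebraically identical with, the group×predictor interaction term
  of a pooled model (which pools residual variance); the pooled model is
  used in tests as an approximate cross-check, and simulation shows the
  implemented statistic holds its nominal size (≈0.046–0.049 at α = 0.05
  over 2000 null cohorts) at the default 45/100 design.
- **Partial correlation**: residualize on covariates plus intercept,
  correlate residuals, `df = n − k − 2`; the Spearman variant
  rank-transforms everything first. Sex is coded 0/1. Constant covariates
  are dropped with a warning; rank deficiency is an error.
- **FDR**: Benjamini–Hochberg per analysis family, one family per report
  table; the run log counts every p-value into exactly one family.
- **Degenerate inputs**: a constant response gives slope 0, r 0, p 1; a
  constant predictor is an error (the slope is unidentified); exact lines
  return p = 0 rather than relying on the t approximation at r = ±1.
- **ANI rule**: impairment is a composite domain T-score below 40 (one SD
  below the normative mean — the conventional operationalization, since
  cutoffs are often left unstated), at least two domains impaired, with
  intact self-reported everyday functioning; the composite, not the
  individual tests, carries the threshold. Both the threshold and the
  count rule are monotone, and the tests check those properties.

## Problem sizes and determinism

The validation suite runs everything at sizes chosen to make the
mathematical guarantees sharp while keeping a full run on one CPU in
about a minute: 32³ phantoms, 100 random SPD tensors for the fit
round-trip, 30 noisy phantom subjects for the error-propagation check,
2000 simulated cohorts for test size and 500 for coverage/power, and
1000 random p-vectors against the brute-force BH definition. `run_study()`
writes display CSVs rounded to 4 decimals plus full-precision
companions, and two runs with the same config and seed are byte-identical.

## Interface

The package is function-first: `run_study()` with a `study_config()` (or
a YAML file via `read_study_config()`) is the entry point, and every
stage is an exported, pipeable function returning tibbles. No shell CLI
is shipped — an R analysis package is its own interface — but the study
config deliberately mirrors what a command-line wrapper would need
(mode, paths, seeds, gating and FDR options), so wrapping `run_study()`
in `Rscript` is a one-liner if a pipeline requires it.

## Known limitations

Single-shell, single-tensor fitting only; no eddy/motion correction,
registration or brain extraction (inputs are assumed template-aligned);
no multi-ROI or tract-based ALPS variants; no bias correction of
predicted ages; covariate control limited to sex; and the cohort
generator's single-coupling-structure design understates the correlated
multiplicity of real per-structure tables, so FDR behavior on real data
with correlated tests is exercised only at the family-bookkeeping level.
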