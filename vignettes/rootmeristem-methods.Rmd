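---
title: "Methods: from single-cell geometry to radial growth mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell geometry to radial growth mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rootmeristem` implements a quantitative pipeline connecting the 3D
geometry of single cells in the *Arabidopsis* root meristem to the radial
growth of the whole organ, under varying brassinosteroid (BR) signalling
(wild type, the loss-of-function receptor mutant *bri1*, and wild type
treated with brassinolide, BL). This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not emulate.

```{r setup}
library(rootmeristem)
```

## Synthetic data

No microscopy is required: every input the pipeline consumes is generated
by a seeded, configurable generator.

**Geometry tables** (`generate_geometry_table()`) emulate per-cell 3D
segmentation exports: five tissues (non-hair and hair epidermis, cortex,
endodermis, pericycle), several roots per condition, per-cell distance
from the quiescent centre (QC), and the five geometric parameters. The
generating model mirrors what the downstream statistics assume: normal
distributions on transformed scales (log length, log depth, raw width)
with linear trends in the square root of distance, additive condition
shifts (high BR lengthens and thins; low BR shortens and widens), a
root-level random intercept, and a two-component length mixture whose
short-component probability decays logistically with distance (calibrated
so the marginal short weight equals the configured value; the default
0.85 reflects that most segmented cells are meristematic). Distances are
drawn uniformly on 4–200 µm. Volume and surface area derive from the
three axis lengths through a cuboid proxy with shape factor 0.85, because
the axis lengths and volume are measured independently in real exports
and no exact shape law holds; tests recompute the proxy exactly.

What the generator does not emulate: segmentation artefacts, spatial
correlation between neighbouring cells, non-Gaussian tails, the lateral
root cap (excluded from analysis), or tissue-dependent distance ranges.
A passing pipeline on synthetic data therefore demonstrates statistical
correctness of the estimators, not robustness to imaging artefacts.

**Displacement tracks** (`generate_tracks()`) integrate the linear
velocity field `v(x) = r (a + b x)` exactly over each 30-min sampling
interval and add Gaussian observation noise to every recorded position.
Defaults (`a` = 0.5 µm/h, `b` = 0.04 1/h, 6 h duration, 0.2 µm noise, 30
cells per condition) give a few µm/h at the end of the meristem, matching
the magnitude of live-imaging measurements. The fold parameter `r`
rescales the whole field, which is how the 0.57-fold (*bri1*) and 3-fold
(BL) conditions are produced.

**4D pairs** (`generate_pairs_4d()`) create lineage-tracked two-time-point
records with linear per-axis growth over `dt` = 12 h, an optional division
that partitions the grown length and volume between two daughters (with
depth/width scattered around the grown value, means preserved), and
advection of the distance coordinate.

**Cross-section meshes** (`generate_mesh()`) build a watertight polygonal
tessellation of the root cross section near the top of the meristem: a
pie of stele cells surrounded by rings of pericycle, endodermis, cortex
and epidermis (default counts 18/12/8/8/20, radii 12/15/19/25/31 µm —
canonical anatomy at the nominal 8 µm section). Interface vertices are
shared between rings, so every internal wall has exactly two incident
cells; ring division angles are staggered by half a spacing so that
neighbouring rings bisect each other's arcs, and the organ-surface arcs
are bisected once, keeping ring polygon areas within about a percent of
the analytic annulus; vertex jitter (default 0.15 µm) breaks the
artificial symmetry.

## Zone classification

Cell length separates meristem from elongation-zone cells. Within each
tissue × condition stratum a two-Gaussian mixture is fitted to raw
lengths by expectation–maximization (`fit_length_mixture()`): median-split
moment initialization, convergence when the log-likelihood increment
falls below 1e-8 (cap 500 iterations), components relabelled so the short
component has the smaller mean. Cells with posterior probability of the
short component strictly above 0.8 are meristem cells
(`classify_meristem()`); strata under 10 cells are skipped with a
warning; variance collapse raises a degenerate-fit error rather than
returning a spurious fit. The posterior is evaluated in log space and
clamped so it stays inside (0, 1], keeping the strict threshold
meaningful at both extremes. Raw (untransformed) lengths are used; with
the bimodal separation observed in practice the choice of scale does not
change labels materially.

## Geometry statistics

Each geometric parameter is first transformed towards normality
(`transform_spec()`: log depth, log length, raw width, square-root
surface area, cube-root volume; distance enters as its square root).
For each tissue × parameter (5 × 5 = 25 models), `fit_mixed_model()`
fits, by REML via `lme4`/`lmerTest`,

```
transformed parameter ~ treatment + sqrt(distance) + (1 | root)
```

on meristem cells. Singular fits (random variance at zero) are retained
with a warning; when every observation is its own root the model falls
back to ordinary least squares — this degenerate limit doubles as a test
oracle. The treatment-term p-value (Satterthwaite F-test, type II) is the
model's headline p-value.

Pairwise treatment contrasts use the single-step max-|t| (Tukey-type)
adjustment from `multcomp::glht` on the fitted covariance; with three
conditions the difference from the exact studentized range is negligible.
Because the model is additive, contrasts do not depend on the distance
covariate value.

Multiplicity is controlled by a two-step adaptive procedure
(`two_step_adaptive_fdr()`): Benjamini–Hochberg over the M model p-values
at α = 0.05; with m1 discoveries, Benjamini–Hochberg over the surviving
models' post-hoc p-values at the adaptive level α·m1/M. The arithmetic is
exact (17 of 25 discoveries gives a stage-2 level of 0.034); the
implementation wraps `p.adjust` and is verified against a brute-force
step-up oracle.

The percent of variance explained by BR signalling decomposes the model
variance into fixed, random-intercept and residual components (computed
directly from the fit: the fixed component is the variance of the fixed
linear predictor over the observations), then multiplies the fixed share
by the treatment proportion of the fixed-term sums of squares. That
proportion is computed from the centred components of the fixed linear
predictor rather than from the F-table: with treatment and distance
sampled independently the two partitions agree in expectation, but the
predictor-based one is on the variance scale the statistic describes.
Type II (each term adjusted for the other) is the default reading; the
terms are orthogonal by design in the synthetic data.

## Kinematics

Per-cell displacement rates are endpoint differences over the full 6-h
window, regressed on starting distance (`fit_displacement()`, with a
warning when R² ≤ 0.9). A cell moving through `v(x) = a + b x`
accelerates during the window, so the endpoint-rate slope `s`
systematically overestimates `b`; the fitted slope is therefore mapped
back through the exact relation `b = log(1 + T s)/T` (and
`a = b·intercept/s`). This matters quantitatively: at `b` = 0.04 1/h and
T = 6 h the raw endpoint slope is 13% high, and a 3-fold condition would
be estimated near 3.9-fold without the correction. Fold-changes are
ratios of fitted slopes, which estimate the generating fold exactly for
proportional fields, whatever the intercept.

Residence time between 8 and 100 µm (the working meristem span) is the
exact integral of `1/v`: `(1/b)·log((a + b·x1)/(a + b·x0))`, with the
uniform-motion and zero-intercept limits handled analytically. By default
the velocity line is anchored at the origin (a = 0), matching how the
linear rate-increase function is used for residence calculations; the
free-intercept form is available. For proportional fields the
residence-time ratio is the inverse rate ratio: a 0.57-fold genotype
spends ≈ 75% longer traversing the meristem.

For genotypes without live imaging,
`relative_rate_from_production()` reproduces the production-rate
bookkeeping: cells produced per day = daily root elongation / mature cell
length; length flux leaving the meristem = that rate × mean meristematic
cell length; residence = meristem length / flux; relative rate = inverse
residence ratio.

## 4D growth rates

`merge_and_rate()` applies the division rule — daughters' lengths and
volumes are summed, depths and widths averaged — and divides the change
by the imaging duration. A 4D anisotropy rate is reported as the per-hour
change of the shape index `length²/(depth·width)` between t0 and the
merged t1; the index itself is the established shape measure and the
per-hour difference is this package's display definition (the quantity is
not given a formula in the literature the package follows).
`filter_meristem_window()` keeps lineages within 60 µm at t0 and 100 µm
at t1. `ancova_rates()` starts from `rate ~ condition × distance` and
drops the interaction when its F-test p-value is ≥ 0.05 (the conventional
reading of "simplify when possible"); condition contrasts are evaluated
at the mean distance via `emmeans` with Benjamini–Hochberg adjustment
within each parameter's contrast family.

## The radial growth simulator

The cross-section mechanics are a mass-spring model, the package's own
concrete formulation of the standard vertex-model ingredients:

* **Walls** are linear-strain springs: tension `k (l − l0)/l0`, with `k`
  (force per unit strain) set per wall class: outer-epidermal,
  epidermal-other, cortex, outer-endodermal, inner-endodermal,
  pericycle-stele.
* **Turgor** loads every wall of a cell with an outward force
  `P × wall length`, split equally between its endpoints; the net force
  on an internal wall is the pressure difference of its two cells. These
  forces are exactly the gradient of the potential
  `Σ ½ k ε² l0 − Σ P·A`.
* **Relaxation** is overdamped: vertices follow the net force until the
  maximum vertex force drops below a tolerance that scales with the
  pressure loading (1e-4 × max pressure × mean rest length). The update
  is preconditioned per vertex by the incident spring stiffness, and the
  production minimizer is FIRE (fast inertial relaxation engine), which
  handles the ill-conditioning of stiff rings over a soft interior; a
  plain preconditioned gradient-descent mode is retained
  (`relax_method = "descent"`) because it descends the potential
  strictly, and the energy-audit test uses it. Both stop at the same
  force criterion and agree on equilibria. Doubling all stiffnesses and
  pressures leaves equilibria and growth trajectories exactly unchanged
  (the step is dimensionless), which is tested.
* **Growth** is stress relaxation: after each relaxation every wall whose
  elastic strain exceeds the threshold (default 0: any tensile strain)
  gains irreversible rest length at rate `ext × (strain − threshold)` per
  step, where `ext` averages the two adjacent cells' extensibility.
  Growth is area-directed (`simulate_to_area()` runs until a target total
  area) or time-directed (a fixed step budget).

**Calibration.** The default parameters are the wild-type reference and
encode the dual-ring picture: stiff outer-epidermal (2000) and
outer/inner-endodermal (1600) walls, intermediate epidermal-other (800)
and cortex (500) walls, softest pericycle-stele walls (300); inner
tissues compensate with higher extensibility (stele/pericycle 0.4 per
step, endodermis 0.24, cortex 0.12, epidermis 0.10) — calibrating
extensibility per tissue is part of fitting the reference, exactly as
wall stiffness is. Turgor declines modestly outward (stele/pericycle
1.6, endodermis 1.3, cortex/epidermis 1.0). The pressure step matters
structurally: with strictly uniform pressure the interior of the
tessellation is displacement-loaded (internal wall strains are set by
geometry, not by their stiffness), and the inner-group stiffness
multiplier then has almost no leverage on inner-tissue area — the
two-multiplier fit would be unidentifiable. A small inward gradient
force-loads the endodermal ring and restores a well-conditioned fit; it
is also physiologically reasonable for inner tissues. The reference run
grows the default 66-cell template to 1.8× its initial area in roughly
260 growth steps; that extension stands in for the growth from the 8 µm
to the 100 µm section on a synthetic template (the real sections'
coordinates are not published), so tissue-specific percentages are
checked directionally and through self-consistency, not against the
printed template-specific values.

With uniform stiffness and extensibility (the `uniform_params()`
baseline) the outer tissues overgrow and the inner tissues undergrow
relative to the calibrated dual-ring run at the same total-area target —
the directional signature that motivates the dual-ring arrangement.

**Stiffness fitting.** `fit_stiffness_multipliers()` searches two
multipliers — inner group: inner-endodermal + pericycle-stele walls;
outer group: outer-epidermal, epidermal-other, cortex, outer-endodermal
walls (the outer-endodermal wall bounds the ring and is assigned
outward; the grouping is configurable in principle since the biological
statement is at tissue level) — by Nelder–Mead in log-multiplier space
from (1, 1), capped at 200 simulator calls, stopping early when the
objective (the maximum relative error of the inner/outer group area
extensions) falls below half the convergence tolerance (default
tolerance 0.1%). The genotype time budget is `round(relative_time × WT
steps)`; relative times come from the kinematics module (1.76 for the
0.57-fold genotype, 0.33 for the 3-fold treatment) rather than from a
table, since residence ratios are the inverse rate ratios for
proportional fields.

## Problem sizes and numerical defaults

The shipped experiments use: 30 tracks per condition over 6 h (20 seed
replicates for fold-change estimates); geometry tables of a few thousand
cells; a 66-cell cross-section template (~280 walls) grown ~260 steps
for the reference, with fitting budgets scaled by relative time. These
sizes make every estimator's sampling error small relative to the
tolerances tested while keeping the whole reproduction run quick on a
single core. Key numerical defaults:
EM tolerance 1e-8; relaxation force tolerance 1e-4 × pressure scale;
dimensionless relaxation step 0.3; growth threshold 0; optimizer cap 200
evaluations with early stop at half the residual tolerance.

## Known limitations

* The simulator is 2D and has no cell division, wall remodelling
  anisotropy, or longitudinal mechanics; extensions of a growing section
  emulate the radial component only.
* The mass-spring formulation (linear-strain springs, per-cell uniform
  pressure, strain-threshold growth) is a minimal standard choice; other
  force or growth laws would change template-specific numbers, which is
  why self-consistency (simulator-generated targets) and directional
  properties are the tested claims.
* Mixed-model treatment tests lean on few biological replicates (roots),
  as in real designs; the type-I error property is checked by simulation
  at the defaults, not proven for arbitrary configurations.
* The endpoint-slope correction in kinematics assumes the velocity field
  is linear in distance within the observed window.
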