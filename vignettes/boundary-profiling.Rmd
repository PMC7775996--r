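---
title: "Depth-resolved boundary profiling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved boundary profiling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the sampling model, the statistics, the synthetic world used to validate
them, and the choices made where the design was genuinely open.

## The measurement model

The unit of analysis is the vertex of a triangulated cortical surface
pair: a *white* surface tracing the gray–white matter (GWM) boundary and
a *pial* surface, vertex-corresponding so that the segment from white
vertex to pial vertex spans the local cortical ribbon. Scalar volumes
(FA, MD, normalized T1 intensity) are sampled at each vertex at five
depths:

* **Gray matter** positions are *projection fractions* of cortical
  thickness along the white→pial correspondence vector: 30% CT targets
  the deeper, more myelinated gray matter, 60% CT the superficial,
  lightly myelinated part.
* **White matter** positions are *absolute* signed distances along the
  inward unit vertex normal: −1 mm targets the short-range association
  (U-)fibres of the superficial white matter, −2 mm the terminations of
  long-range fibres.

The two conventions deliberately differ: fractions follow the ribbon
geometry, absolute depths follow the normal, which is the standard
behaviour of the surface tools this pipeline mirrors. Whether deep
sampling should instead extend the white–pial axis inward is not
determinate from the description we follow; normal-based sampling is the
default and an axis-based variant can be obtained by passing the
normalized white→pial vectors as `normals` to `sample_absolute_depth()`.

Interpolation is trilinear in each volume's own voxel space through its
affine; volumes of different resolution (1 mm structural vs 2.4 mm
diffusion grids) are therefore never resampled onto each other, avoiding
double interpolation. Sample points outside a volume's voxel-centre hull
are **masked, never clamped** — clamping would silently bias statistics
at the volume edge. Masks propagate: a vertex invalid at any depth is
excluded from all statistics.

The gray–white contrast at vertex *i* is

    GWC_i = 100 * (WMI_i − GMI_i) / (0.5 * (WMI_i + GMI_i)),

with WMI the T1 intensity at −1 mm and GMI at 30% CT, i.e. the intensity
difference as a percentage of the local mean intensity. Division by the
mean is the only reading under which the expression is a contrast
measure (and the one consistent with the established contrast of this
type); vertices with `WMI + GMI <= 0` are masked. Whether the
upstream intensities or only the GWC output should be smoothed is not
specified anywhere we could anchor to; the package smooths **final
analysis maps only** (GWC output, each FA/MD depth map) and keeps the
raw maps alongside.

## Smoothing on the mesh

`smooth_vertex_map()` implements iterated discrete heat diffusion
`x <- x + alpha * L x` with **cotangent edge weights** (clamped at zero
for obtuse angles). Uniform graph weights were rejected for a concrete
reason: on a gridded triangulation the diagonal edges make the kernel
anisotropic (the half-maximum width along a coordinate section comes out
~12% low while the variance is on target); cotangent weights give the
discrete Laplace–Beltrami operator, which is isotropic on the sheet.

The iteration count and step size are chosen analytically, not by
trial: one diffusion step adds per-tangent-axis kernel variance
`alpha * mean_i sum_j w_ij |p_j − p_i|^2 / 2`, so for a target FWHM the
total variance `(FWHM / 2.3548)^2` fixes `n_iter` (with `alpha` at most
`0.9 / max weighted degree` for a non-negative kernel) and `alpha` is
then refined so the product is exact. By the central limit theorem the
accumulated kernel is Gaussian to good approximation after the few tens
of iterations a 15 mm kernel needs on a ~1 mm mesh. The update is
symmetric, so the mean over valid vertices is conserved exactly; masked
vertices are removed from the graph, so no weight bleeds across the
mask. Geodesic distance is approximated by the mesh graph metric, which
is adequate at 15 mm FWHM on ~1 mm meshes.

## The vertex-wise model

At every vertex, ordinary least squares for

    Y = b0 + b1*Group + b2*Sex + b3*Group×Sex + b4*Site
        + b5*Age + b6*Age^2 + b7*FSIQ + e

* **Effect codes (−1/+1)** for group, sex, site: with the interaction in
  the model, effect codes keep `b1` interpretable as half the
  sex-averaged group difference and `b3` as the interaction proper. (The
  coding is not stated in the source description; dummy coding would
  make `b1` the group difference *within one sex*.)
* **Continuous covariates are mean-centered across the full sample**;
  the quadratic age term is centered age squared, itself centered, to
  limit collinearity with the intercept and linear term.
* Contrast t-maps are `t = c'b / se(c'b)` with the pooled OLS residual
  df. Nested model comparisons (`nested_f_test()`) implement the step-up
  procedure: a term is a candidate for retention when its vertex-wise
  F-test survives the same cluster-wise correction as the other maps
  (the exact retention rule of the original analysis is not stated; this
  is our documented choice). All added terms in this pipeline are single
  columns, so `F = t^2` exactly and cluster inference on the equivalent
  two-tailed t-map is used — a separate F-field RFT formula would be
  redundant.
* The demographics tests use Welch t with fractional df, while the
  vertex GLM uses pooled OLS df; both conventions appear in the source
  analysis at those respective stages and are deliberately not
  harmonized.
* Rank-deficient designs inside nested comparisons are handled with a
  Moore–Penrose pseudo-inverse (minimum-norm coefficients, correct RSS)
  rather than a hard error, so degenerate columns yield `F = 0` instead
  of aborting a whole map.

## Cluster inference

Smoothness is estimated from **normalized residuals**: for each mesh
edge, `grad^2 = sum_subj (u_i − u_j)^2 / |e|^2` and
`FWHM = sqrt(4 log 2 / grad^2)` (the small-lag relation for a Gaussian
autocorrelation; for discrete white noise it gives the finite value
`h * sqrt(2 log 2)`, which the tests check). Resels per triangle are
`area / FWHM^2` from its own edges; each vertex carries one third of
every incident triangle's resels, so cluster extent in resels is a sum
of vertex shares — this local normalization is what makes the correction
valid for **nonisotropic** smoothness, instead of one global FWHM.

Cluster-level corrected p-values use the standard 2D random-t-field
formulation: expected cluster count per tail from the expected Euler
characteristic at the cluster-defining threshold (CDT), including the
boundary terms of the search region (`R0`, half-perimeter `R1`, `R2`
resels); exponential cluster extents with mean = expected suprathreshold
resel mass / expected cluster count; and a Poisson-clumping family-wise
probability across **both tails**, matching the two-tailed p < .05
cluster criterion. The CDT itself is nowhere stated in the source
description; the default is two-tailed p = 0.001 (`cdt_p` argument), the
convention of the toolbox family this analysis descends from, and the
regime where RFT cluster p-values are calibrated.

Because the exact resel-estimation variant of the original toolbox is
unspecified, correctness is asserted against a **Freedman–Lane
permutation test** (`permutation_cluster_test()`): reduced-model
residuals are permuted so nuisance covariates are respected, and the
null of the maximum cluster resel extent gives empirical family-wise
p-values. The test suite requires both methods to hold their family-wise
error on null simulations and to agree within a factor of 3 in the
informative p-range.

## Overlap statistics

Binary maps mark vertices inside clusters significant after correction.
`overlap_summary()` reports `100 |A∩B| / |denominator|`, where the
denominator is the **diffusion-measure map** (the convention of the
reported percentages: "out of all FA-altered vertices, how many also
show a GWC alteration"). Pairwise prevalence χ² tests compare
suprathreshold counts between measures as 2×2 tables with **Yates
continuity correction** — the correction is never named in the source,
but recomputing all three printed χ² values (and both demographic χ²
values) from the printed counts matches the corrected statistic and not
the uncorrected one, which the acceptance tests pin down; the
uncorrected form stays available behind `correct = FALSE`.

The simulation null generates pairs of random vertex-wise difference
maps. Whether the original random maps were spatially smoothed or
count-matched is not stated ("random t-values … thresholded"); both
readings are shipped: `mode = "iid"` (default) thresholds independent
standard-normal values at two-tailed p < 0.05, `mode =
"prevalence_matched"` draws uniformly random vertex sets of the observed
sizes. Under iid thresholding the expected overlap percentage equals the
threshold prevalence (~5%), a closed form the tests verify; the
exceedance probability uses the `(1 + #{≥ obs}) / (N + 1)` estimator,
floored at `1/(N+1)`.

## The synthetic world

The generator is the package's study stand-in, not a demo. Defaults
encode the cohort conditions of the motivating study design: two groups
(ASD/TD) × two sexes × two sites with 23 subjects per cell (184 total),
ages uniform on 18–52 years, FSIQ ~ N(115, 11²), mean cortical thickness
2.67 mm (SD 0.1 across vertices). Tissue profiles are sigmoids across
the boundary between plateaus chosen at textbook adult values — T1
intensity 110 (WM) / 90 (GM) in arbitrary normalized units, FA 0.45 /
0.15, MD 7.5e-4 / 8.5e-4 mm²/s — with a 0.5 mm transition width.
Spatially correlated noise is made by smoothing white volume noise to
6 mm FWHM (matching the smoothness assumption RFT requires), with
per-modality SDs (2, 0.03, 4e-5) giving boundary contrast-to-noise in
the range where planted effects of a few noise SDs are detectable at
n ≈ 20–40/group — the study's effect *sizes* are not reported (only
suprathreshold extents), so magnitudes were fixed once at values
producing comparable qualitative behaviour, not fitted to any number.

Planted effects are hard discs (contiguous vertex sets, exact ground
truth) in a modality, depth range, and cell pattern: `"group"` effects
shift ASD subjects, `"group_x_sex"` effects shift with the product of
the ±1 codes. A per-subject dose (mean 1, SD 0.3) scales the planted
effects, and the AQ-like clinical score of ASD subjects is a linear
function of that dose plus noise calibrated to a target correlation
(default 0.6) — giving the clinical-correlation stage a recoverable
signal. Age affects volumes not at all by default (the age terms then
test as nuisance covariates only).

The slab is the default test world because every expectation is exact
there: normals are (0,0,1), grid vertices coincide with voxel centres,
sigmoid profiles evaluate in closed form, and FWHM can be measured on a
transect. The sphere variant (subdivided icosahedron; up to one
subdivision every vertex neighbourhood is rotationally symmetric, so
normals are exactly radial) exercises curvature. What the generator does
**not** emulate: gyrification, partial-volume mixtures, scanner
artifacts, registration error, site-dependent intensity scales. Passing
tests therefore demonstrate correctness of the estimators under their
stated assumptions, not robustness to real-data pathologies.

## Numerical choices and degenerate inputs

* Points exactly on the voxel-hull boundary are valid (tolerance 1e-9);
  the top interpolation cell is closed so `coord = dim − 1` samples the
  last voxel exactly.
* Zero-noise inputs give zero residual variance: such vertices are
  masked in t-maps, smoothness estimation reports failure, and the
  pipeline then skips cluster inference while keeping coefficients (the
  noise-free recovery path in the tests).
* Cluster tables order by descending resel extent; the empty
  suprathreshold set is an empty table, not an error.
* `rft_cluster_p()` uses `expm1` so corrected p-values of huge clusters
  underflow gracefully instead of collapsing to 0 and breaking
  monotonicity.
* Every random draw descends from one master seed via named substreams
  (`substream_seed()`), which is what makes whole-run outputs bitwise
  reproducible.

## Problem sizes used by the test suite

Chosen as the smallest sizes at which the distributional checks have
power: null t/F calibration at 5,000–20,000 vertices; family-wise error
on 200 null datasets of 676 vertices with 24 subjects and 150
permutations; planted-effect power and recovery at 40 subjects/group on
a 26×26 slab; the overlap null at the full 327,684-vertex scale with
5,000 simulations (a few minutes) and at 50,000 vertices elsewhere.

## Known limitations

* Graph-distance smoothing mildly underestimates geodesic distance on
  strongly curved meshes; at 15 mm FWHM on ~1 mm meshes the error is
  negligible, on coarse spheres it is not.
* RFT cluster p-values inherit the usual high-CDT assumption; at CDTs
  much above p = 0.01 trust the permutation branch instead.
* The overlap null models spatial independence (or count-matching), not
  the spatial autocorrelation of real t-maps; spin-test-style nulls are
  out of scope.
* Vertex correspondence across subjects is by index on a shared template
  mesh; spherical registration to a template is upstream of this
  package.
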