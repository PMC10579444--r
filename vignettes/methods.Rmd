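---
title: "Methods: synthetic coronary trees, cone-beam simulation, and multi-stage 3D reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic coronary trees, cone-beam simulation, and multi-stage 3D reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coronary3d)
```

## The problem

Quantifying coronary artery disease from X-ray angiography requires a 3D
model of the vessel tree, but an angiographic acquisition only provides
2D projections, typically with imprecisely recorded gantry angles and
distances. `coronary3d` implements, at desk scale, a complete study
environment for this reconstruction problem: a generator of ground-truth
right-coronary-tree geometries, a cone-beam projection simulator that
renders binary angiogram silhouettes, a learning-based reconstructor
that maps distance-transformed silhouettes directly to 3D geometry
*without any knowledge of the acquisition geometry*, a classical
epipolar-geometry reconstructor that does consume the true geometry (the
comparator), and the error metrics used to judge both.

Everything operates on one container: the tree matrix, an `M x N x 4`
array holding `(x, y, z, r)` in millimetres for `M` branches and `N`
ordered centerline points per branch. A tree is therefore an analytical
object — tube surfaces, arclengths, and stenosis severities all derive
from it in closed form.

## Synthetic tree generator

Each tree consists of the four main right-coronary branches (RCA, SA,
AM, PDA). Branch shapes come from hand-built templates: control points
of a natural cubic spline (chord-length parameterized), each perturbed
by isotropic Gaussian noise with per-point scales of 2–4 mm. The nominal
templates were drawn to match typical right-dominant anatomy (an RCA of
roughly 110 mm sweeping the atrioventricular groove; a short cranial SA
branch proximally; an AM branch across the free wall at mid-level; a PDA
descending the posterior interventricular groove) and are fully
configurable; no claim of statistical fidelity to any patient population
is made. Side-branch origins are re-anchored onto the *sampled* RCA
polyline inside fixed parametric take-off windows (SA proximal, AM mid,
PDA distal), so topology survives randomization.

Radii follow a linear taper from a sampled proximal `r_max` to a distal
`r_min` (rejection-sampled to keep `r_min < r_max`). Stenoses are
multiplicative Gaussian narrowings

\[ r'(t) = r(t)\,\bigl(1 - \tfrac{s}{100}\,
   e^{-(t - t_0)^2 / 2\sigma^2}\bigr), \]

with severity `s` (percent diameter reduction at the lesion centre,
uniform in 20–90 %), centre `t0` (uniform in 0.15–0.85) and width
`sigma` (uniform in 0.02–0.08 of the branch's parametric length). Per
tree, 0/1/2 lesions occur with probability 0.40/0.45/0.15, restricted
to RCA and PDA by default. Trees are augmented as rigid units: an Euler
rotation (SD 10° per axis), with probability 0.5 a unit-diagonal shear
(coefficients up to ±0.1), and with probability 0.5 a smooth warp (sum
of three 3D cosine displacement modes, 2 mm amplitude, 60 mm spatial
scale — low-frequency on purpose, so vessels stay vessel-like).

Choices worth flagging: severity is defined *relative to the local
lesion-free taper*, which keeps the definition self-consistent at any
`t0`; invalid random draws are re-sampled rather than clipped, avoiding
probability pile-up at the bounds; `N = 100` points per branch resolves
sub-millimetre features on 30–150 mm branches while keeping network
output heads small.

## Cone-beam projection simulator

A view places a point source on a sphere of radius `SOD` around the
isocenter at azimuth/elevation `(theta, phi)`, with the detector plane
perpendicular to the source–isocenter ray at distance `SID` from the
source. Defaults are typical C-arm values — `SOD` 750 mm, `SID`
1200 mm, 512 px over a 200 mm field (0.390625 mm/px, magnification
1.6) — all configurable; none are claimed to reproduce a specific
scanner. Acquisition protocols draw each view uniformly from a
20-degree window around one of five standard working views (LAO 45,
RAO 30, cranial AP, LAO-caudal, RAO-cranial).

A pixel is foreground exactly when its source ray passes within the
local (linearly interpolated) radius of some centerline segment — an
exact line–capsule test on the piecewise-linear centerline. This avoids
meshing and ray-tracing artifacts entirely; the triangulated
`tube_surface()` exists for visualization and export, not for
rendering. There is no anti-aliasing, detector noise, attenuation
physics, contrast dynamics or cardiac motion: the output is the ideal
binarized angiogram a perfect segmentation would produce, which is the
representation the reconstruction method is defined on. The patient is
fixed at the isocenter across all views of one tree.

The network input is the Euclidean distance transform of each binary
image (foreground pixels carry the distance in pixels to the nearest
background pixel; an isolated pixel has value 1). The EDT ridge traces
the projected centerline and its height the projected radius, so a
single smooth field implicitly encodes both quantities. The transform
itself is delegated to `EBImage::distmap` and verified exactly against
a brute-force computation in the tests.

## The multi-stage network

The reconstructor stacks its `k` input distance maps as channels of one
backbone pass (channel order = ascending view index), and regresses:

* **centerline stage** — one MLP with hidden layers 1024/1024/1024/512
  (ReLU, batch normalization between hidden layers) onto the
  `M x N x 3` coordinate block;
* **radius stage** — one MLP of 128/128/128 *per branch* onto that
  branch's `N` radii.

The radius stage is trained with plain MSE over all points. The
centerline stage adds an arclength regularizer: with branch arclengths
`S`, the loss is the coordinate MSE plus
`lambda / batch_size * sum_branches |S_truth - S_pred|`, `lambda = 0.1`.
The absolute value is a deliberate choice: the literal signed
difference is unbounded below (it would reward arbitrarily long
predictions) and is available behind `signed = TRUE` for completeness.
Vessel length matters because it is a primary determinant of the
pressure gradient along a vessel, the quantity clinical indices are
built on.

The single-stage comparator uses the same backbone and one
1024/1024/1024/512 head regressing the full `M x N x 4` matrix under a
weighted loss: mean over points of (squared coordinate error + `mu` ×
squared radius error). `mu` defaults to the balancing rule — the ratio
of coordinate to radius MSE measured on the first epoch, frozen
thereafter — which puts both terms on the same order of magnitude.

Why multi-stage at all: stenosis points are a tiny fraction of the
output matrix, so in a joint loss their misfit is diluted and the
cheapest way to reduce loss is to predict the smooth taper. Dedicated
per-branch radius heads trained (and then fine-tuned with the backbone
frozen) on radius-only MSE amplify exactly those points.

Both models train with Adam (learning rate 5e-4, L2 weight decay 1e-4),
batch size 8; the multi-stage model runs a joint phase and then 50
per-branch fine-tuning epochs. Training consumes only distance maps and
ground-truth matrices — there is deliberately no code path through
which view geometry can reach the model, and a test asserts this
"uncalibrated" contract on the function signatures.

Numerical choices: inputs are scaled by the dataset-wide maximum;
coordinate targets are standardized with per-axis means but one
*shared* SD (per-axis SDs would distort geometry anisotropically and
corrupt the arclength term); radii are standardized by mean/SD. Losses
are computed in millimetre space by de-standardizing predictions inside
the trainer, so `lambda` and `mu` keep physical units. After training,
batch-normalization inference statistics are set by one calibration
pass over the training set — at desk-scale step counts the usual
momentum running averages lag far behind and would corrupt inference.
All training is a pure function of (data, seed).

The backbone is pluggable behind `backbone_spec()`. The implemented
extractor is `tiny_conv` — four 3×3 convolution blocks (8/16/32/64
filters, ReLU, 2×2 average pooling) feeding a flat feature vector —
which is the right size for the CPU-scale studies this package runs.
Larger extractors (ResNet-class, transformer-class) can be supplied via
the `builder` hook; the architecture above does not change.

## Projection-geometry baseline

The comparator consumes two binary projections *plus their true view
geometries* and reconstructs the centerline classically:

1. **2D centerlines** — Zhang–Suen thinning, iterative pruning of spurs
   shorter than 8 px, and ordering from the endpoint nearer the top of
   the image (head-up convention; ties broken by column). Two
   refinements matter in practice and are part of the method: the
   skeleton ends are extended along their tangent while the distance
   map stays on its in-tube plateau (thinning retracts ends by roughly
   the local radius, which would otherwise shift the whole arclength
   parameterization), and the ordered pixel chain is smoothed to
   sub-pixel precision with a light smoothing spline (quantization
   jitter otherwise inflates chord length and drifts the
   parameterization).
2. **Epipolar candidates** — for each reference point, up to 10
   second-image centerline points within 2 px of its epipolar line,
   nearest first.
3. **Refinement** — dynamic programming over the candidate lattice
   minimizing epipolar distance + two-view reprojection error of the
   triangulated point, under a hard monotone ordering constraint on the
   second-centerline index (the classical ordering constraint; points
   with no candidates stay unmatched).
4. **Triangulation** — midpoint of the common perpendicular of the two
   pixel rays; pairs with rays closer than 0.1° to parallel are
   dropped.
5. **Spline** — a chord-length parameterized cubic spline through the
   triangulated points, resampled at `N` uniform parameter values.
   Radii are not reconstructed (`r = 0`): the baseline is a centerline
   method.

The epipolar band width, candidate cap, spur length and smoothing level
are configuration, not claims about any published implementation.

## Evaluation

Metrics operate on index-corresponding points (the fixed `M x N x 4`
representation carries the correspondence; no closest-point matching):
centerline RMSE (Euclidean, over all points), radius RMSE, vessel-length
MAE (mean absolute arclength difference over branches), and stenosis
MAE — the absolute difference of minimum radii within the lesion window
`t0 ± 3σ`, averaged over lesions, and *absent* (not zero) for trees
without lesions. `percent_diameter_reduction()` inverts the lesion
model: the lesion-free reference is interpolated linearly across the
window from the radii just outside it, and severity is the largest
pointwise diameter reduction inside the window; the round trip through
`apply_stenoses()` recovers commanded severities within 0.5 percentage
points across the whole 20–90 grid.

Two harnesses reproduce the package's headline comparisons:

* `run_stress_set()` — 10 base vessels × severities 20–90 % in 5 %
  steps = 150 geometries, each projected and reconstructed by both
  models.
* `run_dtheta_sweep()` — 5 vessels × 6 angular separations Δθ between
  15° and 90°, first view fixed at (θ = −45°, φ = 0); the baseline
  reconstructs from full-resolution images with true geometry, the
  network from reduced-resolution distance maps without it.

## Desk-scale study conditions

The comparison studies run on one CPU, so their problem sizes are
scaled down deliberately and stated here once: single vessels with
`N = 20` points; two views (nominal LAO 45 / RAO 45, 20° windows) on
96 px detectors with 2.0 mm pixels (same 1.6 magnification, 192 mm
field, so whole vessels stay in view); 200 training samples; 25 joint
epochs + 50 radius fine-tuning epochs (losses plateau by epoch ~20 at
this scale). Full-scale defaults (N = 100, four branches, 512 px,
0.390625 mm/px, 5 views / 3 inputs, 300 + 50 epochs, 4500/500 split)
remain the package defaults and are what `generate_dataset()` and
`view_sampler()` produce out of the box.

At 2 mm pixels a healthy lumen is ~1.6 px wide, so moderate stenoses
are at the edge of visibility in the binary silhouette — both models
inherit this floor, and stenosis errors grow with severity for both.
The qualitative contrast survives the scaling: the single-stage model's
stenosis error grows several-fold from mild to severe lesions, while
the multi-stage model stays more accurate in the severe regime and
sub-pixel at every severity. Global radius RMSE at this scale
(~0.15 mm) is consistent with what dedicated radius heads are designed
to deliver.

The angle sweep carries a caveat the reader should keep in mind: the
desk-scale model is trained on the two-working-view protocol (inter-view
angles near 90°), so sweep pairs with small Δθ evaluate it well outside
its training distribution, and there the geometry-consuming baseline is
clearly stronger. Making the network competitive across the whole sweep
would require training across a wide range of inter-view angles (the
sampler supports per-view windows for exactly this), which at this
training budget measurably dilutes the stenosis comparison; the package
reports the sweep numbers as computed rather than trading one study's
fidelity against the other's.

## What passing tests do and do not show

The generator emulates geometry, not imaging: binary silhouettes are
ideal segmentations, free of noise, motion, table panning, and
segmentation artifacts; trees are static and right-coronary only; the
lesion model is smooth and concentric. Results on this synthetic corpus
therefore demonstrate the *mechanics* of the method — losses,
architecture, geometry, and the direction of the multi- vs single-stage
effect — and say nothing about clinical angiograms, scanner-specific
geometry, or population anatomy. Degenerate inputs are handled
explicitly: degenerate spline draws are re-sampled (capped retries),
near-parallel ray pairs are dropped with a warning, views with
coincident sources refuse epipolar work, blank or multi-component
images are rejected by the centerline extractor, and predicted radii
are floored at 0.01 mm to keep reconstructed matrices valid.

## Reproducibility

Every randomized entry point either takes a seed or documents that it
uses the global RNG; seeded functions restore the RNG state on exit.
`run_pipeline()` persists its configuration (seed included) next to its
artifacts and derives per-stage seeds deterministically from the root
seed, so generator/projection stages are bit-reproducible from the
persisted configuration. `scripts/acceptance.R` recomputes the
package's acceptance quantities from scratch under a caller-supplied
seed.
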