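---
title: "Carpal bone segmentation and freeze-thaw volumetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carpal bone segmentation and freeze-thaw volumetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patient-specific scaphoid prostheses are modelled from CT scans of cadaver
wrists. Two questions dominate the preclinical modelling workflow:

1. **Does frozen storage change the bone?** Cadaver specimens are stored at
   about −20&nbsp;°C and often imaged frozen. If freezing altered scaphoid
   volume or shape, a prosthesis designed from a frozen scan would not fit
   the thawed wrist. The volumetric comparison is a paired design: the same
   wrist is scanned repeatedly in each condition, each scan is segmented,
   and the per-scan mesh volumes are compared with a paired *t*-test.
2. **Does prosthesis-grade smoothing distort the model?** A prosthesis
   surface must articulate smoothly against cartilage, so the segmentation
   is deliberately smoothed — but Gaussian smoothing of a *thin* cortical
   shell widens the shell (a point-spread effect) and inflates the model.

`carposeg` implements both analyses as a tested pipeline. Because no CT
data accompany the workflow, a synthetic phantom generator with analytic
ground truth stands in for the specimen; every downstream stage is
validated against closed forms or brute-force oracles.

## Segmentation model

A bone is extracted from a Hounsfield-unit volume in four stages:

1. **Threshold-connected region growing** from a user seed placed in the
   cortical layer: the connected component of `{lower <= HU <= upper}`
   containing the seed. Foreground connectivity is 6 (face neighbours);
   hole filling uses the complementary 26-connected background, the
   standard pairing that avoids topological paradoxes. The default band is
   `[1150, Inf)` HU, separating cortical bone from trabecular bone and soft
   tissue.
2. **Hole filling**: background cavities not 26-connected to the grid
   border become foreground, closing the trabecular interior behind the
   cortical shell.
3. **Laplacian level-set refinement**. The image is smoothed with a
   Gaussian of physical width σ (per-axis voxel widths σ/spacing); the
   Laplacian of the smoothed image — whose zero crossings mark intensity
   edges — is the propagation speed. A signed Euclidean distance transform
   of the mask (anisotropic spacing, negative inside) initializes the
   front, which then evolves with a Godunov upwind scheme plus a
   mean-curvature regularizer so the zero level locks onto the edge:
   the tight workflow uses σ = 0.3&nbsp;mm and 20 iterations, the smooth
   workflow σ = 1.0&nbsp;mm and 30 iterations. Iteration counts are part of
   the protocol: the front is *refined*, not evolved to convergence.
4. **Zero-level mesh extraction** by marching tetrahedra (below).

### The smooth (prosthesis-ready) workflow

Smoothing a thin bright shell widens it: blurring turns the shell into a
ridge whose inflection points move apart, and the level set follows them
outward. The smooth workflow removes the thin layer before smoothing:

* region growing + filling (no level set),
* erosion of the mask by 0.5&nbsp;mm *physical* radius,
* refill of the image under the eroded mask with 2106&nbsp;HU (the nominal
  cortical intensity), producing a solid object whose only edge is the
  outer surface,
* the standard chain (σ = 1.0&nbsp;mm, 30 iterations) on the adapted image.

On a thin-shell sphere phantom the naive σ=1.0 segmentation inflates the
volume by ≈14% while the refill variant stays within 1% of the tight
volume — the mitigation the procedure exists for. Erosion is implemented
through the Euclidean distance transform (a voxel survives if its centre is
more than the radius from the nearest background centre), the
physical-space reading of "0.5&nbsp;mm" on an anisotropic grid.

## Numerical choices

* **Speed normalization.** The Laplacian is normalized by its maximum
  absolute value over the *border-unaffected interior* (a 4σ margin from
  the grid faces). Replicate-padded smoothing kinks the field at the faces,
  and on a small phantom grid that spurious border Laplacian would
  otherwise set the speed scale and stall the front; in a clinical volume
  the maximum sits on bone edges. The time step follows the advective CFL
  bound (0.4·min spacing per unit speed) tightened by the parabolic bound
  of the curvature term; propagation and curvature weights default to
  1.0 and 0.2.
* **Distance-transform initialization.** Felzenszwalb–Huttenlocher
  separable squared-distance transforms with per-axis spacing give the
  exact Euclidean signed distance of the voxelized mask.
* **Mesh extraction** uses marching tetrahedra on the Freudenthal 6-tet
  cube split with linear interpolation along tet edges. Unlike classic
  marching cubes it has no ambiguous cases, so the surface is guaranteed
  closed and 2-manifold; vertices are deduplicated by grid-edge key and
  exact zeros are nudged to the outside so that intersections are strictly
  interior to edges. Triangles are oriented outward (away from the
  negative, inside region) — negating the level set reproduces the same
  surface with flipped orientation.
* **Degenerate inputs.** Single-sign level sets ("no zero level"), empty
  initializations, out-of-band seeds and masks annihilated by erosion all
  raise explicit, stage-tagged errors rather than returning empty results.

## Mesh metrics

* **Volume** is the divergence-theorem sum of signed origin-tetrahedron
  volumes `det(v0, v1, v2)/6` over triangles, translation-invariant on
  closed meshes and positive for outward orientation. Open meshes are
  rejected with the boundary-edge count.
* **Registration** is trimmed point-to-surface ICP: nearest points on the
  fixed surface via an axis-aligned bounding-volume hierarchy, trimming at
  the 95th percentile of correspondence distances against outliers, and
  the Kabsch/SVD rigid update. The transform with the lowest observed RMS
  is returned, making the reported RMS non-increasing by construction.
* **Signed distance maps** sample at the reference mesh vertices (so the
  included count is one number). The magnitude is the exact
  nearest-triangle distance (BVH-accelerated; validated against exhaustive
  search to 1e-9); the sign comes from the angle-weighted pseudonormal of
  the closest feature — face, edge or vertex — which classifies inside and
  outside correctly for closed meshes even arbitrarily near the surface.
  The test suite cross-checks the sign against an independent generalized
  winding-number oracle. Positive means the reference surface lies outside
  the other mesh ("reference larger"). Summaries (min/max/mean/SD,
  sample convention) are reported for signed and absolute values.
* **Joint-space thickness** between two bones restricts the reference
  vertices to an articular region — nearest point on the other bone within
  5&nbsp;mm and outward normal within 60° of the direction to it (both
  configurable; an articular region was plausibly delineated manually in
  clinical practice, and these defaults make it reproducible) — and
  reports the per-vertex nearest distance and its minimum. Interpenetration
  is a precondition violation; an empty region is an explicit "no facing
  surface" result, never a silent zero.

## Paired statistics and reporting conventions

For paired volumes (condition A = frozen, B = thawed), differences
`d_i = b_i − a_i` give `t = mean(d)/(s_d/√n)` with df `n−1`, the two-sided
*p*, the 95% CI `mean(d) ± t_{0.975,df}·s_d/√n`, and Cohen's
`d = mean(d)/s_d`. Conventions chosen to reproduce the bundled example
table exactly:

* per-scan relative difference `100·(thawed − frozen)/thawed` — the thawed
  volume is the denominator (the only convention consistent with every
  per-scan value in the bundled table);
* the per-scan column is reported as an absolute value, while the summary
  mean is the mean of *signed* values;
* the summary SD of relative differences uses the population convention
  (divisor n), whereas column SDs of raw volumes use the sample convention
  (n−1); both conventions are reported explicitly;
* when every difference is exactly zero the test is defined as t = 0,
  p = 1.

## The phantom generator

The generator emulates a small carpal bone: an ellipsoid or a two-lobe
smooth-max blend (a waisted, scaphoid-like outline), a cortical shell of
configurable thickness between an outer surface and an inner surface with
semi-axes reduced by the shell thickness, a trabecular interior, soft-tissue
background, optional iid Gaussian HU noise, and an optional second
"capitate-like" body at a controlled surface gap for joint-space tests.
Defaults: voxel spacing 0.17 × 0.17 × 0.2&nbsp;mm (a high-resolution wrist
CT protocol), cortical 2106&nbsp;HU, trabecular 300&nbsp;HU, background
40&nbsp;HU, noise SD 20&nbsp;HU, shell 0.75&nbsp;mm. The trabecular,
background and noise levels are not calibrated to any scanner; they are
chosen so the threshold band separates the tissue classes by at least five
noise SDs. Ellipsoid truth volumes are closed-form (`4/3·π·abc`); blended
shapes get their truth volume from fine-grid quadrature at 10× oversampling,
so every shape carries a numeric oracle. Pose is applied to the shape, never
to the grid, avoiding resampling ambiguity.

Condition pairs for the freeze–thaw design scale condition B isotropically
so its true volume is exactly `(1 + perturbation)` times condition A's;
replicate pairs differ only by fresh noise draws.

**What the phantom does not model** — and hence what passing tests do not
show about real data: no scanner point-spread function, beam hardening,
partial-volume blur, or repositioning between scans. In particular,
replicate variability under iid voxel noise is far below clinical
scan-to-scan variability (volume CV ≈ 0.002% here versus a few tenths of a
percent in practice, which is driven by acquisition geometry): the
level set is nearly invariant to intensity noise. The null/power
Monte-Carlo is therefore conservative in its effect-detection claim — a 3%
true volume change is detected essentially always — while the null size
(≈5% rejections) is informative as measured.

## Problem sizes

The test suite and the acceptance script use 6&nbsp;mm-radius sphere
phantoms at wrist-protocol spacing for volume recovery, reproducibility (10 noisy
replicates) and the smoothing ablation (0.6&nbsp;mm shell), and
4&nbsp;mm-radius spheres for the Monte-Carlo (20 simulated experiments × 10
pairs × 2 conditions, null and 3%-perturbation arms) — sizes at which each
experiment completes in minutes on one core while the voxel counts
(≈0.5M per volume) keep discretization error well inside the asserted
bounds. Coarser 0.4&nbsp;mm grids back the brute-force oracle comparisons.

## Known limitations

* The level-set front is refined for a fixed iteration count, not evolved
  to convergence; volumes inherit a small, workflow-dependent bias
  (≈+0.7% on a 6&nbsp;mm sphere for the tight workflow) that cancels in
  paired comparisons.
* The Laplacian edge definition carries the classic curvature bias
  (zero crossings sit ≈2σ²/r outside a convex edge), which is why smooth
  segmentation of small convex bodies must not be run to convergence.
* Signed distances are sampled at vertices only; sub-facet extremes are
  missed on coarse meshes (densification is configurable off by default).
* The generator's noise model is iid; see above for what that implies.
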