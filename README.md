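# carposeg

Carpal-bone segmentation, mesh metrics and freeze–thaw volumetry in R.

`carposeg` is for researchers modelling small carpal bones (the scaphoid in
particular) from CT for patient-specific prosthesis design. It answers two
workflow questions as a tested, reproducible pipeline:

* **Does frozen storage change the bone?** Repeated scans of one specimen
  in two conditions (frozen / thawed) are segmented, and the per-scan mesh
  volumes are compared with a paired *t*-test, confidence interval and
  effect size.
* **Does prosthesis-grade smoothing distort the model?** Strong Gaussian
  smoothing widens a thin cortical shell and inflates the segmented bone;
  the package implements the mitigation — erode the mask by 0.5 mm and
  refill the interior at the cortical intensity (2106 HU) before smooth
  re-segmentation — and quantifies the effect with signed surface-distance
  maps.

## Methods at a glance

* **Segmentation**: threshold-connected region growing from a cortical seed
  (band `[1150, ∞)` HU), hole filling, Laplacian level-set refinement
  (propagation speed = Laplacian of the Gaussian-smoothed image; tight
  workflow σ = 0.3 mm / 20 iterations, smooth workflow σ = 1.0 mm / 30
  iterations), and zero-level mesh extraction by marching tetrahedra
  (closed, outward-oriented, 2-manifold meshes in mm).
* **Mesh metrics**: divergence-theorem volume
  `V = Σ det(v₀, v₁, v₂)/6`; trimmed point-to-surface ICP registration;
  per-vertex signed distance maps (sign by angle-weighted pseudonormals:
  positive where the reference surface is larger); joint-space thickness
  over an articular region defined by a distance cap and a facing-angle
  limit.
* **Statistics**: paired `t = mean(d)/(s_d/√n)` with df `n−1`, 95% CI,
  Cohen's `d = mean(d)/s_d`, per-scan relative differences
  `100·(thawed − frozen)/thawed`, and both SD conventions reported
  explicitly.
* **Phantoms**: a synthetic CT generator (cortical shell / trabecular
  interior / background, 0.17 × 0.17 × 0.2 mm voxels, optional second body
  at a controlled gap) with closed-form or quadrature ground-truth volumes,
  so the whole pipeline is testable without cadaver data.

See the methods vignette (`vignettes/carposeg-methods.Rmd`) for the model,
numerical choices and limitations.

## Worked example

The package ships a ten-scan frozen/thawed volume table
(`inst/extdata/table1.csv`). The full paired comparison:

```r
library(carposeg)
tab <- read_volume_pairs(system.file("extdata", "table1.csv", package = "carposeg"))
run_comparison(table = tab)
#> Frozen vs thawed volume comparison (n = 10)
#>   column means: 1257.43 / 1259.21 mm^3 (SD 7.85 / 3.98)
#> Paired t-test: mean difference 1.78 (s_d 7.27), t(9) = 0.77, p = 0.46
#>   95% CI [-3.43, 6.98], Cohen's d = 0.24
#>   mean signed relative difference 0.14% (population SD 0.55%)
```

The mean frozen–thawed difference (1.78 mm³, about 0.14% of the bone) is
far from significant (p = 0.46) with a small effect size (d = 0.24): the
freeze–thaw contrast does not measurably change the segmented volume.

The same machinery runs end-to-end on synthetic data:

```r
ph <- generate_phantom(phantom_spec(semi_axes = c(6, 6, 6), shell_mm = 0.75,
                                    noise_sd = 0))
ph$truth$outer_volume                      # 904.7787 (= 4/3 * pi * 6^3)
m <- tight_segment(ph$volume, ph$truth$seed_voxel)
mesh_volume(m)                             # 910.93  (+0.68% of truth)
```

A thin command-line dispatcher over the same functions is installed at
`inst/cli/carposeg.R` (`phantom`, `segment tight|smooth`, `mesh
volume|register|compare|jst`, `stats`, `run` subcommands).

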