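# mesoreg

Benchmarking 3D co-registration of sparse vascular networks imaged with
raster-scan photoacoustic mesoscopy.

Mesoscopic photoacoustic imaging resolves perfused vasculature at ~10 µm
resolution a few millimetres into tissue, label-free. Tracking how a
vascular network evolves — across repeated scans in one session, or across
days of tumour growth — requires co-registering volumes that are
notoriously awkward: vessels occupy a few percent of the voxels,
intensities drift from scan to scan, light fluence decays with depth, and
vessels genuinely appear and disappear between time points. `mesoreg`
implements five families of co-registration for this regime and a complete
harness to benchmark them on synthetic vascular phantoms with known ground
truth, so every stage is testable without any imaging data:

| Method | Class | Input | Transform |
|---|---|---|---|
| `register_affine` + `similarity_metric("mi")` | intensity, mutual information | volumes | rigid/affine |
| `register_affine` + `similarity_metric("ncc")` | intensity, normalised cross-correlation | volumes | rigid/affine |
| `register_distance` | shape, NCC on Euclidean distance maps | masks | rigid/affine |
| `icp_point_to_plane` | shape, point-to-plane ICP on surfaces | masks | rigid |
| `train_deformable` / `register_deformable` | weakly supervised encoder–decoder | volumes + masks | dense displacement field |

The intensity metrics are `MI(F,G) = H(F) + H(G) − H(F,G)` over binned
histograms and the centred, norm-scaled dot product
`NCC = Σ(f−f̄)(g−ḡ) / [Σ(f−f̄)² Σ(g−ḡ)²]^{1/2}`, both maximised by
gradient ascent with finite-difference gradients. The ICP cost is
`Σᵢ ((T gᵢ − fᵢ)·ηᵢ)²` over nearest-neighbour correspondences with surface
normals η. The deformable model minimises the unweighted sum
`L = −NCC + GDL + L_BE`, where GDL is the generalised Dice loss with
inverse-squared-volume label weights and `L_BE` the mean squared Hessian
(bending energy) of the displacement field. Quality is scored pre vs post
with Dice, symmetric mean/Hausdorff surface distances (µm), MI, SSIM and
landmark target registration error (TRE, µm); methods are compared
pairwise with exact Wilcoxon signed-rank tests under Holm–Bonferroni
correction (m = 10 for five methods).

The phantom generator (`generate_vessel_tree`, `make_pair`) grows random
branching vessel trees in a thin anisotropic slab (default 20 × 20 × 4 µm
voxels), rasterises them exactly, applies a known rigid transform or smooth
displacement field, drops/adds terminal vessels, and passes both scans
through a depth-decay + gain + noise imaging model. Branch points become
landmarks whose moving positions are the ground truth applied exactly.

## A worked example

```r
library(mesoreg)

# simulate a repositioned re-scan of the same vascular bed
g <- grid3d(c(128, 128, 64), spacing = c(20, 20, 4))   # 2.56 x 2.56 x 0.26 mm
tree <- generate_vessel_tree(g, seed = 7)
gt <- sample_affine(max_translation_um = 150, max_rotation_rad = 5 * pi / 180,
                    seed = 3, center = grid_centre(g))
pair <- make_pair(tree, g, gt,
                  variability = list(dropout_fraction = 0.1, extra_vessel_count = 1),
                  seed = 11)
pair
#> <phantom_pair> 7 landmarks, gt = affine3d, dropout = 0.1, gain factor = 0.815
#> <grid3d> 128 x 128 x 64 voxels, spacing (20, 20, 4) um, origin (0, 0, 0) um

# register with NCC after standard pre-processing
f <- clip_and_zscore(pair$fixed$volume)
m <- clip_and_zscore(pair$moving$volume)
res <- register_affine(f, m, similarity_metric("ncc"))
res
#> <registration_result> ncc: 26 iterations, converged, final value 0.436

# landmark error before and after
pred <- transform_points(res$transform, pair$landmarks_fixed)
dimnames(pred) <- dimnames(pair$landmarks_fixed)
c(pre_tre_um = tre(pair$landmarks_fixed, pair$landmarks_moving),
  post_tre_um = tre(pred, pair$landmarks_moving))
#>  pre_tre_um post_tre_um
#>    83.10035    19.20806

# mask overlap before and after
warped_mask <- warp(pair$moving$mask, res$transform)
c(pre_dice = dice(pair$moving$mask, pair$fixed$mask),
  post_dice = dice(warped_mask, pair$fixed$mask))
#>  pre_dice post_dice
#> 0.3211222 0.8558621
```

The registration pulls the branch-point landmarks from an 83 µm initial
error down to ~19 µm (one in-plane voxel) and raises mask Dice from 0.32
to 0.86. `run_benchmark(benchmark_config(...))` runs all five methods over
a set of simulated pairs, aggregates the percent-change panel and the
pairwise statistics, and (optionally) writes CSV reports, magenta/green
MIP overlays (`render_mip_overlay`) and a provenance record.

The methods vignette (`vignettes/mesoreg-methods.Rmd`) documents the
models, parameter meanings and defaults, numerical choices, and what the
phantoms do and do not emulate.

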