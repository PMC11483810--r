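---
title: "Benchmarking co-registration of sparse vascular mesoscopy volumes"
author: "mesoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking co-registration of sparse vascular mesoscopy volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Raster-scan photoacoustic mesoscopy resolves perfused vasculature at ~10 um
resolution down to a few millimetres of depth, without contrast agents:
haemoglobin absorbs pulsed 532 nm light and the resulting thermoelastic
pressure waves are detected by a raster-scanned high-frequency transducer.
Monitoring how a vascular network changes — across repeated scans on one
day, or across days of tumour growth — requires co-registering volumes that
are hard to align: the signal is sparse (a few percent of voxels are
vessel), intensities vary from scan to scan, light fluence decays with
depth, and vessels genuinely appear and disappear between time points.

`mesoreg` implements and benchmarks five families of co-registration for
this regime, entirely on synthetic vascular phantoms with known ground
truth:

1. **Affine, intensity-based, mutual information (MI)** — gradient ascent on
   `MI(F, G) = H(F) + H(G) - H(F, G)` over binned intensity histograms.
2. **Affine, intensity-based, normalised cross-correlation (NCC)** — the
   centred, norm-scaled voxel-wise dot product.
3. **Affine, shape-based, distance maps** — both segmentations are replaced
   by exact Euclidean distance transforms (which weight vessel centre lines
   most strongly) and registered with NCC.
4. **Affine, shape-based, point-to-plane ICP** — surfaces extracted from the
   segmentations are aligned by iterated closest-point matching with the
   point-to-plane cost `sum(((T g_i - f_i) . n_i)^2)`.
5. **Deformable, weakly supervised** — a 4-level 3D encoder-decoder maps the
   stacked fixed/moving intensity + segmentation channels to a dense
   displacement field (DDF), trained on
   `L_total = -NCC + GDL + L_BE` with no ground-truth supervision.

Registration quality is scored pre vs post with Dice, symmetric mean and
Hausdorff surface distances, MI, SSIM and landmark target registration
error (TRE), and methods are compared pairwise with Wilcoxon signed-rank
tests under Holm–Bonferroni correction (family size 10 for five methods).

## Conventions

* All physical coordinates are micrometres; voxel indices are 0-based and
  refer to voxel centres. The default acquisition grid spacing is
  20 x 20 x 4 um (in-plane x depth), matching mesoscopy reconstructions.
* An `affine3d` maps **fixed-space physical coordinates to moving-space
  coordinates**; warping pulls moving intensities back through this map
  onto the fixed grid (trilinear for volumes, nearest-neighbour for masks).
* A `ddf` stores per-voxel displacements in voxel units of the fixed grid;
  `warp_with_ddf` resamples `x(v + u(v))`, thresholding warped masks at
  0.5. TRE for a deformable result maps a fixed landmark as
  `T_init(p + u(p))` and measures distances in moving space.

## The phantom generator

`generate_vessel_tree` grows a random binary branching tree of straight
tubular segments inside a thin slab, with tapering radii and branch points
recorded as landmark candidates; trees are redrawn deterministically until
at least three bifurcations exist, because the benchmark needs landmarkable
anatomy. `rasterize_tree` marks a voxel as vessel iff its centre lies
within the segment radius (exact point-to-segment distance), with a linear
one-voxel soft edge on the intensity channel.

`make_pair` builds a fixed/moving scan pair:

* **Geometric ground truth** — a sampled rigid transform (repositioning
  between repeated scans) or a smooth random displacement field
  (longitudinal change). Smooth fields are white noise on a coarse control
  grid of cell size `smoothness_scale_um`, trilinearly upsampled and
  rescaled so the maximum displacement equals `amplitude_um`; larger scales
  give lower bending energy by construction.
* **Biological variability** — a fraction of terminal segments is dropped
  (only terminals, and only where the parent keeps another child, so deeper
  branch points survive and no interior segment silently becomes terminal),
  and optionally new terminal segments appear in the moving scan.
* **Imaging physics** — intensity = `background + gain * clean *
  exp(-decay * z_mm)` plus Gaussian noise; the moving scan's gain is
  multiplied by a logged random factor in [0.8, 1.2] to emulate scan-to-scan
  technical variability.
* **Landmarks** — branch points that remain bifurcations in both trees;
  their moving positions are the ground-truth map applied exactly, so the
  pre-noise TRE of the recorded transform is identically zero.

Default study conditions, chosen once: rigid pairs use translations up to
150–200 um and rotations up to 5–10 degrees (manual repositioning scale);
longitudinal-analogue pairs use 60 um smooth deformations at 500 um
smoothness; noise SD 0.08–0.1 against unit vessel intensity (SNR >= 10);
dropout 5–10 % of terminals. The rigid-recovery experiments use dropout 0,
mirroring same-day repeated scans where minimal biological change is
expected. What the generator does **not** model: reflection and shadow
artefacts, melanin absorption, limited-view reconstruction streaks, or
motion artefacts — passing benchmarks here demonstrate correctness of the
methods under controlled geometry, not robustness to every real-world
confound.

## Pre-processing

The chain runs in fixed order, each stage independently switchable:
high-pass (hard FFT mask along depth at `cutoff x Nyquist`, default 0.01 —
the filter axis and cutoff are free design choices, as echo noise is
low-frequency along depth), 3x3 slice-wise adaptive Wiener filtering with
the slice-mean local variance as noise power (window statistics truncated
at slice borders so constant slices pass through unchanged), slice-wise
rolling-ball background removal implemented as greyscale opening with a
Euclidean disk (radius 5 px), then volume-wise 0.05–99.95 percentile
clipping followed by slice-wise z-scoring (epsilon-guarded), which
equalises vessel weight across depth. Percentiles are computed volume-wise
because slice-wise clipping would re-introduce depth-dependent scaling
before the z-score.

The EBImage morphology engine pads image borders with zeros; `mesoreg`
shifts slice intensities so the pad can never win the erosion minimum or
the dilation maximum, recovering standard "ignore outside" flat-kernel
morphology for arbitrarily signed slices.

## Affine optimisation

Both intensity metrics are maximised by gradient ascent over a 6-parameter
rigid transform (optional 12-parameter affine), composed with a
centre-of-mass or landmark initialisation; rotations pivot about the fixed
volume's centre. Gradients are central finite differences; each iteration
steps along the normalised gradient in a scaled parameter space (50 um per
translation unit, 0.05 rad per rotation unit) with a backtracking line
search that starts from the preset learning rate and only ever halves —
the step is never grown, so the preset rate bounds every move. Iteration
stops at 100 iterations, when the metric changes by less than 1e-8, or when
the line search finds no ascent direction; the best transform visited is
returned, which guarantees the optimised metric never ends below its
initial value.

Numerical choices that matter:

* During optimisation the metric is evaluated on the fixed grid subsampled
  by stride 2 (configurable); the final warp always uses the full grid.
  This is the standard sampling trade-off and changes recovered transforms
  by well under a voxel on the phantoms.
* MI uses 50 equal-width bins per image. The moving image's bin edges are
  frozen at its global (unwarped) range so bin boundaries cannot shift with
  the candidate transform.
* Finite-difference steps are 1 um / 0.001 rad for NCC. Histogram MI
  carries sub-voxel resampling ripple (measurably, MI can dip exactly at
  the optimum with local peaks a few um away), so its gradient is probed at
  10 um / 0.01 rad — below that scale the FD gradient reads ripple, not
  slope, and the optimiser stalls.

`register_distance` resamples both masks to isotropic spacing (the in-plane
20 um, minimising z-upsampling error), computes exact Euclidean distance
transforms (separable lower-envelope algorithm, anisotropy-aware), and runs
the same NCC machinery on the distance maps.

## Surfaces and ICP

`extract_surface` samples the 0.5 iso-level of the isotropically resampled
binary field by edge crossing: every foreground/background 6-neighbour pair
contributes one vertex at the midpoint of the two voxel centres — exactly
the vertex locations a one-step-per-voxel marching-cubes pass places on a
binary field — with the outward face direction as its normal.

`icp_point_to_plane` treats the moving cloud as the source. Each iteration
matches every transformed moving point to its nearest fixed point within
`max_corr_dist` (default 10 voxels; uniform-grid hashing), solves the
small-angle linearised point-to-plane least squares for a 6-dof increment,
re-orthonormalises, and composes. The RMS point-to-plane residual trace is
kept non-increasing by construction: the first iteration that would
increase it terminates the loop with the previous transform.

## The deformable network

The network takes 4 channels in fixed order — fixed intensity, fixed
segmentation, moving intensity, moving segmentation — after rigid
pre-alignment (centre-of-mass by default, landmarks optionally) and min-max
intensity normalisation, and predicts a 3-channel DDF on the same grid.
Architecture: 4 encoder levels (3^3 convolutions + ReLU, 2x average
pooling; default channels 4/8/16/32), a bottleneck, and a mirrored decoder
with nearest-neighbour upsampling and skip concatenation, closed by a
1x1x1 head. All weights are He-initialised; the head is additionally
scaled by 0.01 so the initial field is near zero and training starts from
an identity warp. Input dimensions must be divisible by 2^4 = 16
(centre-cropping is applied otherwise).

Training is weakly supervised: the loss is
`-NCC(fixed, warped moving) + GDL(fixed seg, warped soft seg) + BE(DDF)`,
an unweighted sum. GDL weights the two labels by the inverse squared fixed
label volume, which is what keeps ~1 % foreground from being ignored.
Bending energy is the mean squared Hessian (voxel-unit central second
differences, evaluated where the stencil fits, mixed terms counted twice),
zero for globally affine fields. Gradients flow through the trilinear
warp analytically (the spatial gradient of the interpolant), and the whole
backward pass is verified against finite differences in the test suite.
Optimisation is Adam at batch size 1; optional augmentation applies a
shared random z-rotation (up to pi/15 rad) to both scans of a pair.

Desk-scale defaults are deliberate: channels 4/8/16/32, 64^3-class crops
and 25–200 epochs make single-CPU training take minutes. The learning-rate
default is 1e-3; a full-scale schedule (~10^3 epochs over tens of pairs,
i.e. ~50x more optimisation steps) pairs with 1e-4, which at desk scale
moves the loss imperceptibly. Best-validation-loss model selection is used
when a validation set is supplied, best-training-loss otherwise. Training
is bit-reproducible for a fixed seed under single-threaded BLAS; with a
threaded BLAS, reduction order can perturb results at floating-point
round-off level.

## Initialisation policy in the benchmark

Repeated-scan (rigid ground truth) pairs are initialised from centres of
mass. Longitudinal-analogue (smooth ground truth) pairs are initialised by
rigid landmark alignment for every method that accepts an initial
transform — MI, NCC, and the deformable model's pre-alignment — which is
the standard protocol when the anatomy has visibly changed between scans
and branch points can be identified in both: centre-of-mass alignment is
unreliable once vessels have appeared or disappeared asymmetrically. ICP
needs no initialisation and the distance-map method keeps centre-of-mass
initialisation as part of its definition. At desk scale this policy is
what lets the deformable method express its advantage on longitudinal
pairs: starting from the best rigid fit, its dense field corrects the
residual non-rigid motion, whereas the affine methods can only trade off
landmark accuracy against global intensity similarity.

## Evaluation and statistics

Surfaces for MD/HD are border voxels under 6-connectivity on the
isotropically resampled grid; distances are physical and computed exactly
via the distance transform of the opposite surface set, which the tests
pin against an O(n^2) double loop. HD is the true maximum, not a
percentile. SSIM uses the two-term form with C1 = (0.01 L)^2,
C2 = (0.03 L)^2, L the fixed volume's dynamic range, over a 7^3 truncated
box window (or global statistics with `window = NULL`). Percent change is
`100 (post - pre) / |pre|`; a zero pre value (e.g. fully disjoint masks)
yields NA rather than a division error, and such pairs drop out of the
paired tests.

The Wilcoxon signed-rank test drops zero differences, uses midranks, and
enumerates all 2^n sign assignments exactly for n <= 15 (ties included);
above that it uses the tie-corrected normal approximation without
continuity correction. Holm's step-down adjustment accepts a family size
`m` at least as large as the number of p-values; `compare_methods` runs the
10 pairwise comparisons of 5 methods per metric at m = 10.

## Benchmark sizes and runtimes

The shipped experiments are sized for a single CPU: rigid-recovery runs use
20 pairs on the native-resolution 128 x 128 x 64 grid (a few minutes);
deformable training criteria use 4 pairs at 64^3 for 50 epochs (~5 min);
the five-method benchmark uses 12 pairs (half rigid, half smooth) at
64 x 64 x 32 with 25 training epochs. The full native 600 x 600 x 750
grid and 10^3-epoch training remain available through the same
configuration objects.

## Known limitations

* The phantom slab is thin and vessels are mostly in-plane; severe
  out-of-plane rotations are under-represented.
* Histogram MI (hard binning) is noisier than Parzen-windowed variants;
  the FD probe scale compensates but a Parzen implementation would be the
  natural upgrade.
* The deformable model is intentionally small; at desk scale it recovers
  smooth fields' large-scale structure, not capillary-level deformation.
* No multi-resolution pyramid is used anywhere, by design — robustness to
  initial misalignments much larger than the metric's capture range relies
  on centre-of-mass or landmark initialisation.
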