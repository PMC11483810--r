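# Synthetic phantom generator: trees, rasterisation, imaging model,
# ground-truth transforms and pair construction.

test_that("vessel tree generation is seeded-deterministic and respects the domain", {
  g <- small_grid()
  bp_small <- list(depth = 4, branch_prob = 0.9, radius_range = c(10, 20),
                   tortuosity = 0.2)
  t1 <- generate_vessel_tree(g, bp_small, seed = 7)
  t2 <- generate_vessel_tree(g, bp_small, seed = 7)
  expect_identical(t1$segments, t2$segments)
  t3 <- generate_vessel_tree(g, bp_small, seed = 8)
  expect_false(identical(t1$segments, t3$segments))

  # depth 1: a single unbranched root, no branch points
  t_deg <- generate_vessel_tree(g, list(depth = 1, branch_prob = 1,
                                        radius_range = c(10, 20), tortuosity = 0.1),
                                seed = 3)
  expect_equal(nrow(t_deg$segments), 1L)
  expect_equal(nrow(tree_branch_points(t_deg)), 0L)

  # depth 4, seed 7: every branch point inside the physical bounding box
  t4 <- generate_vessel_tree(g, list(depth = 4, branch_prob = 0.9,
                                     radius_range = c(10, 20), tortuosity = 0.2),
                             seed = 7)
  bp <- tree_branch_points(t4)
  lo <- g$origin
  hi <- g$origin + grid_extent(g)
  expect_true(all(sweep(bp, 2, lo, `>=`) & sweep(bp, 2, hi, `<=`)))

  # all segment endpoints also stay inside the domain
  segs <- t4$segments
  pts <- rbind(as.matrix(segs[, c("x0", "y0", "z0")]),
               as.matrix(segs[, c("x1", "y1", "z1")]))
  expect_true(all(sweep(pts, 2, lo, `>=`) & sweep(pts, 2, hi, `<=`)))

  expect_error(generate_vessel_tree(g, list(depth = 0)), "depth")
  expect_error(generate_vessel_tree(g, list(depth = 3, radius_range = c(30, 10))),
               "inverted")
  expect_error(generate_vessel_tree(g, list(depth = 3, radius_range = c(10, 1e5))),
               "radius_range")
})

test_that("rasterisation marks exactly the voxels within radius of the axis", {
  g <- grid3d(c(40, 20, 12), c(20, 20, 20))
  # single segment along x, radius 30 um
  tree <- structure(list(segments = data.frame(
    id = 1L, parent = 0L, gen = 1L,
    x0 = 100, y0 = 200, z0 = 110, x1 = 600, y1 = 200, z1 = 110, radius = 30),
    domain = g), class = "vessel_tree")
  ras <- rasterize_tree(tree, g)
  idx <- which(ras$mask$values == 1, arr.ind = TRUE)
  pts <- mesoreg:::index_to_physical(g, idx - 1)
  # brute-force point-to-segment distance for every foreground voxel
  seg_dist <- function(p) {
    a <- c(100, 200, 110); b <- c(600, 200, 110)
    t <- pmin(pmax(sum((p - a) * (b - a)) / sum((b - a)^2), 0), 1)
    sqrt(sum((p - (a + t * (b - a)))^2))
  }
  d_in <- apply(pts, 1, seg_dist)
  expect_true(all(d_in <= 30 + 1e-9))
  # ... and every background voxel is farther than the radius
  idx0 <- which(ras$mask$values == 0, arr.ind = TRUE)
  pts0 <- mesoreg:::index_to_physical(g, idx0 - 1)
  d_out <- apply(pts0, 1, seg_dist)
  expect_true(all(d_out > 30 - 1e-9))

  # region far from the tree carries no mask
  expect_true(all(ras$mask$values[, , 1] == 0))

  # segment order does not change the rasterisation
  tree2 <- tree
  tree2$segments <- rbind(tree$segments,
                          data.frame(id = 2L, parent = 1L, gen = 2L, x0 = 600, y0 = 200,
                                     z0 = 110, x1 = 700, y1 = 300, z1 = 130, radius = 20))
  tree3 <- tree2
  tree3$segments <- tree3$segments[2:1, ]
  expect_identical(rasterize_tree(tree2, g)$mask$values,
                   rasterize_tree(tree3, g)$mask$values)
})

test_that("imaging model applies depth decay, gain and seeded noise as specified", {
  g <- grid3d(c(8, 8, 251), c(20, 20, 4))  # 1 mm depth at slice 251
  clean <- volume3d(array(1, g$shape), g)
  # identity parameters pass the volume through unchanged
  out_id <- apply_imaging_model(clean, list(depth_decay_per_mm = 0, gain = 1,
                                            gaussian_noise_sd = 0, background_level = 0))
  expect_identical(out_id$values, clean$values)
  # decay ln 2 per mm halves the signal at 1 mm depth
  out_dec <- apply_imaging_model(clean, list(depth_decay_per_mm = log(2), gain = 1,
                                             gaussian_noise_sd = 0, background_level = 0))
  expect_equal(out_dec$values[1, 1, 251] / out_dec$values[1, 1, 1], 0.5, tolerance = 1e-12)
  # two noise seeds agree in the mean within 3 standard errors over 10^3 voxels
  g2 <- grid3d(c(10, 10, 10), c(20, 20, 4))
  cl2 <- volume3d(array(0.5, g2$shape), g2)
  p <- list(depth_decay_per_mm = 0, gain = 1, gaussian_noise_sd = 0.2, background_level = 0)
  m1 <- mean(apply_imaging_model(cl2, p, seed = 1)$values)
  m2 <- mean(apply_imaging_model(cl2, p, seed = 2)$values)
  se <- 0.2 / sqrt(1000)
  expect_lt(abs(m1 - m2), 3 * sqrt(2) * se)
  # deterministic per seed
  expect_identical(apply_imaging_model(cl2, p, seed = 5)$values,
                   apply_imaging_model(cl2, p, seed = 5)$values)
  expect_error(apply_imaging_model(clean, list(depth_decay_per_mm = -1)), "negative")
})

test_that("sampled rigid transforms are rigid and respect their bounds", {
  expect_equal(sample_affine(0, 0, seed = 1)$matrix, diag(4))
  for (s in 1:5) {
    t <- sample_affine(200, pi / 15, seed = s, center = c(100, 100, 50))
    R <- t$matrix[1:3, 1:3]
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_lte(rotation_angle(t), pi / 15 + 1e-12)
  }
  expect_error(sample_affine(-1, 0), "bounds")
})

test_that("smooth deformation fields are bounded, scale-controlled and seeded", {
  g <- small_grid(c(32, 32, 16))
  expect_true(all(sample_smooth_deformation(g, 0, 300, seed = 1)$vectors == 0))
  f <- sample_smooth_deformation(g, 50, 300, seed = 4)
  mag_um <- sqrt((f$vectors[, , , 1] * g$spacing[1])^2 +
                 (f$vectors[, , , 2] * g$spacing[2])^2 +
                 (f$vectors[, , , 3] * g$spacing[3])^2)
  expect_lte(max(mag_um), 50 + 1e-9)
  # doubling the smoothness scale lowers the bending energy (fixed seed/amplitude)
  be1 <- bending_energy(sample_smooth_deformation(g, 50, 200, seed = 4))
  be2 <- bending_energy(sample_smooth_deformation(g, 50, 400, seed = 4))
  expect_lt(be2, be1)
  expect_identical(sample_smooth_deformation(g, 50, 300, seed = 9)$vectors,
                   sample_smooth_deformation(g, 50, 300, seed = 9)$vectors)
})

test_that("phantom pairs carry exact ground truth and controlled variability", {
  # identity transform, no dropout, no noise: the two scans are identical
  p0 <- tiny_pair(gt = NULL, dropout = 0, noise = 0)
  expect_equal(dice(p0$fixed$mask, p0$moving$mask), 1)

  # rigid ground truth maps fixed landmarks onto moving ones exactly
  g <- small_grid()
  gt <- sample_affine(120, 4 * pi / 180, seed = 2, center = grid_centre(g))
  p1 <- tiny_pair(gt = gt, dropout = 0.1, noise = 0.05)
  expect_lt(max(abs(apply_affine(gt, p1$landmarks_fixed) - p1$landmarks_moving)), 1e-6)

  # dropout arithmetic: moving terminals = round(0.7 x fixed terminals) + extras
  tree <- generate_vessel_tree(g, list(depth = 5, branch_prob = 1,
                                       radius_range = c(10, 20), tortuosity = 0.15),
                               seed = 21)
  nt_fixed <- length(mesoreg:::tree_terminals(tree))
  pr <- make_pair(tree, g, NULL,
                  variability = list(dropout_fraction = 0.3, extra_vessel_count = 2),
                  imaging_params = list(gaussian_noise_sd = 0), seed = 5)
  nt_moving <- length(mesoreg:::tree_terminals(pr$moving_tree))
  expect_equal(nt_moving, round(0.7 * nt_fixed) + 2)

  expect_error(make_pair(tree, g, NULL, variability = list(dropout_fraction = 1)),
               "dropout")
})

test_that("resampling the moving mask through the inverse ground truth recovers the fixed mask", {
  # vessels several voxels thick, so boundary discretisation stays small
  g <- grid3d(c(64, 64, 64), c(20, 20, 10))
  gt <- sample_affine(100, 4 * pi / 180, seed = 6, center = grid_centre(g))
  tree <- generate_vessel_tree(g, list(depth = 4, branch_prob = 0.9,
                                       radius_range = c(100, 140), tortuosity = 0.2),
                               seed = 13)
  pr <- make_pair(tree, g, gt, variability = list(dropout_fraction = 0),
                  imaging_params = list(gaussian_noise_sd = 0), seed = 3)
  # pull the moving mask back through gt (nearest neighbour): discretisation
  # is the only source of mismatch
  recovered <- warp(pr$moving$mask, gt, grid = g)
  expect_gte(dice(recovered, pr$fixed$mask), 0.95)
  # landmark TRE of gt-warped landmarks is exactly zero before noise
  pred <- apply_affine(gt, pr$landmarks_fixed)
  dimnames(pred) <- dimnames(pr$landmarks_fixed)
  expect_lt(tre(pred, pr$landmarks_moving), 1e-9)
})
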