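# Similarity metrics, initialisation strategies, warping and gradient-ascent
# affine registration.

vol_from <- function(x) volume3d(array(x, c(length(x), 1, 1)), grid3d(c(length(x), 1, 1)))

test_that("mutual information matches hand-computed entropies", {
  # identical images: MI equals the marginal entropy
  f <- random_volume(c(6, 6, 4), seed = 1)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  fi <- mesoreg:::bin_indices(as.numeric(f$values), 50L)
  hF <- h(tabulate(fi, 50) / length(fi))
  expect_equal(mutual_information(f, f, 50), hF, tolerance = 1e-12)

  # independent 2-bin example: uniform joint -> MI = 0
  fa <- vol_from(c(0, 0, 1, 1))
  gb <- vol_from(c(0, 1, 0, 1))
  expect_equal(mutual_information(fa, gb, 2), 0, tolerance = 1e-12)
  # perfectly dependent 2-bin example -> MI = ln 2
  gc_ <- vol_from(c(0, 0, 1, 1))
  expect_equal(mutual_information(fa, gc_, 2), log(2), tolerance = 1e-12)

  # symmetry and bounds: 0 <= MI <= min of the marginal entropies
  g <- random_volume(c(6, 6, 4), seed = 2)
  expect_equal(mutual_information(f, g, 32), mutual_information(g, f, 32),
               tolerance = 1e-12)
  expect_gte(mutual_information(f, g, 32), -1e-12)
  hof <- function(v) {
    p <- tabulate(mesoreg:::bin_indices(as.numeric(v$values), 32L), 32) / length(v$values)
    p <- p[p > 0]; -sum(p * log(p))
  }
  expect_lte(mutual_information(f, g, 32), min(hof(f), hof(g)) + 1e-9)
  expect_error(mutual_information(f, random_volume(c(5, 5, 4), seed = 1)), "grid")
})

test_that("NCC obeys its closed-form identities", {
  f <- random_volume(c(5, 5, 5), seed = 3)
  aff <- volume3d(2.5 * f$values + 7, f$grid)
  expect_equal(ncc(f, aff), 1, tolerance = 1e-12)
  neg <- volume3d(-f$values, f$grid)
  expect_equal(ncc(f, neg), -1, tolerance = 1e-12)
  # hand computation: f = (1,2,3), g = (1,2,4) -> 3 / sqrt(2 * 14/3)
  fv <- vol_from(c(1, 2, 3)); gv <- vol_from(c(1, 2, 4))
  expect_equal(ncc(fv, gv), 3 / sqrt(2 * (14 / 3)), tolerance = 1e-12)
  # symmetry; constant input errors
  g <- random_volume(c(5, 5, 5), seed = 4)
  expect_equal(ncc(f, g), ncc(g, f), tolerance = 1e-14)
  expect_error(ncc(f, volume3d(array(1, f$grid$shape), f$grid)), "constant")
})

test_that("centre-of-mass initialisation recovers pure translations", {
  g <- grid3d(c(32, 32, 16), c(20, 20, 4))
  vals <- array(0, g$shape)
  vals[8:12, 10:14, 6:10] <- 1
  f <- volume3d(vals, g)
  moved <- warp(f, affine_translation(c(-100, 0, 0)))  # content shifts +100 um in x
  t <- com_initialize(f, moved)
  expect_equal(t$matrix[1:3, 4], c(100, 0, 0), tolerance = 20)
  # identity and intensity-scaling invariance
  expect_equal(com_initialize(f, f)$matrix, diag(4), tolerance = 1e-9)
  t2 <- com_initialize(f, volume3d(5 * moved$values, g))
  expect_equal(t2$matrix, t$matrix, tolerance = 1e-9)
  expect_error(com_initialize(volume3d(array(0, g$shape), g), f), "mass")
})

test_that("landmark initialisation recovers exact rigid transforms", {
  set.seed(10)
  lf <- matrix(runif(15, 0, 1000), 5, 3, dimnames = list(paste0("p", 1:5), NULL))
  R <- mesoreg:::rotation_euler(0.1, -0.2, 0.3)
  tr <- c(50, -30, 20)
  lg <- t(R %*% t(lf)) + matrix(tr, 5, 3, byrow = TRUE)
  rownames(lg) <- rownames(lf)
  t <- landmark_initialize(lf, lg)
  expect_lt(max(abs(apply_affine(t, lf) - lg)), 1e-9)
  expect_equal(det(t$matrix[1:3, 1:3]), 1, tolerance = 1e-12)
  # identity case and label-order invariance
  expect_equal(landmark_initialize(lf, lf)$matrix, diag(4), tolerance = 1e-9)
  t_perm <- landmark_initialize(lf[c(3, 1, 5, 2, 4), ], lg)
  expect_equal(t_perm$matrix, t$matrix, tolerance = 1e-9)
  # degenerate configurations are rejected
  col_f <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  expect_error(landmark_initialize(col_f, col_f + 10), "collinear")
  expect_error(landmark_initialize(lf[1:2, ], lg[1:2, ]), "3")
})

test_that("warping is exact for identity and integer-voxel shifts, and invertible", {
  p <- tiny_pair(noise = 0.05)
  v <- p$fixed$volume
  expect_identical(warp(v, affine_identity())$values, v$values)
  # one-voxel translation equals an array roll with zero fill
  t1 <- affine_translation(c(v$grid$spacing[1], 0, 0))
  w <- warp(v, t1)
  expect_equal(w$values[1:(dim(v$values)[1] - 1), , ], v$values[2:dim(v$values)[1], , ],
               tolerance = 1e-12)
  expect_true(all(w$values[dim(v$values)[1], , ] == 0))
  # mask round trip through a small rigid transform
  g <- grid3d(c(64, 64, 64), c(20, 20, 10))
  tree <- generate_vessel_tree(g, list(depth = 4, branch_prob = 0.9,
                                       radius_range = c(100, 140), tortuosity = 0.2),
                               seed = 5)
  m <- rasterize_tree(tree, g)$mask
  t <- affine_rigid(rotation = c(0, 0, 3 * pi / 180), translation = c(60, -40, 10),
                    center = grid_centre(g))
  roundtrip <- warp(warp(m, t), invert_affine(t))
  expect_gte(dice(roundtrip, m), 0.98)
  expect_error(warp(v, affine3d(diag(c(1, 1, 1, 1)) + 0)), NA)
})

test_that("self-registration stays at the identity and the trace contract holds", {
  p <- tiny_pair(noise = 0.03)
  f <- clip_and_zscore(p$fixed$volume)
  res <- register_affine(f, f, similarity_metric("ncc"),
                         opts = optimizer_settings(max_iterations = 20))
  # probe points: landmark TRE under the estimated transform < 1 in-plane voxel
  pred <- transform_points(res$transform, p$landmarks_fixed)
  dimnames(pred) <- dimnames(p$landmarks_fixed)
  expect_lt(tre(pred, p$landmarks_fixed), 20)
  # best-so-far metric is non-decreasing along the trace and >= start
  expect_gte(res$final_value, res$initial_value)
  if (length(res$metric_trace) > 1)
    expect_true(all(diff(cummax(res$metric_trace)) >= 0))
  expect_lte(res$iterations, 20)
})

test_that("registration recovers a known rigid motion on a noisy phantom pair", {
  g <- grid3d(c(96, 96, 48), c(20, 20, 4))
  tree <- generate_vessel_tree(g, list(depth = 5, branch_prob = 0.9,
                                       radius_range = c(15, 30), tortuosity = 0.2),
                               seed = 31)
  gt <- compose_affine(affine_translation(c(200, 100, 20)),
                       affine_identity())
  pair <- make_pair(tree, g, gt, variability = list(dropout_fraction = 0.05),
                    imaging_params = list(depth_decay_per_mm = 0.5, gain = 1,
                                          gaussian_noise_sd = 0.08,
                                          background_level = 0.05), seed = 8)
  f <- clip_and_zscore(pair$fixed$volume)
  gmov <- clip_and_zscore(pair$moving$volume)
  res <- register_affine(f, gmov, similarity_metric("ncc"))
  pred <- transform_points(res$transform, pair$landmarks_fixed)
  dimnames(pred) <- dimnames(pair$landmarks_fixed)
  expect_lt(tre(pred, pair$landmarks_moving), 40)  # two in-plane voxels
})
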