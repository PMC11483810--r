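# Deformable registration: losses, displacement-field warping, network
# construction and the training loop.

test_that("generalised Dice loss matches a direct evaluation of its formula", {
  g <- grid3d(c(2, 2, 2), c(1, 1, 1))
  mf <- binary_mask(array(c(1, rep(0, 7)), c(2, 2, 2)), g)
  # disjoint single-voxel foregrounds: evaluate the two-label formula by hand
  gm_vals <- array(c(0, 1, rep(0, 6)), c(2, 2, 2))
  gm <- binary_mask(gm_vals, g)
  eps <- 1e-8
  w1 <- 1 / (1 + eps)^2; w0 <- 1 / (7 + eps)^2
  num <- w1 * 0 + w0 * 6          # bg overlap: 6 voxels background in both
  den <- w1 * (1 + 1) + w0 * (7 + 7)
  expect_equal(gdl_loss(mf, gm), 1 - 2 * num / den, tolerance = 1e-9)
  # identical masks give zero loss
  expect_lt(gdl_loss(mf, mf), 1e-9)
  # random mask pairs stay within [0, 1]
  for (s in 1:100) {
    a <- random_mask(c(6, 6, 6), p = 0.3, seed = s)
    b <- random_mask(c(6, 6, 6), p = 0.3, seed = s + 100)
    v <- gdl_loss(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("bending energy vanishes for affine fields and matches closed forms", {
  g <- grid3d(c(8, 8, 8), c(1, 1, 1))
  # constant field
  expect_equal(bending_energy(ddf(array(0.7, c(8, 8, 8, 3)), g)), 0)
  # linear (affine) field: u(x) = A x + b has zero second derivatives
  co <- expand.grid(i = 0:7, j = 0:7, k = 0:7)
  lin <- array(0, c(8, 8, 8, 3))
  lin[, , , 1] <- array(0.3 * co$i - 0.2 * co$j + 0.1 * co$k + 1, c(8, 8, 8))
  lin[, , , 2] <- array(-0.5 * co$i + 0.25 * co$k, c(8, 8, 8))
  lin[, , , 3] <- array(0.05 * co$j, c(8, 8, 8))
  expect_equal(bending_energy(ddf(lin, g)), 0, tolerance = 1e-20)
  # quadratic u_x = x^2: second difference 2 at interior voxels, squared = 4
  n <- 8
  quad <- array(0, c(n, n, n, 3))
  quad[, , , 1] <- array(rep((0:(n - 1))^2, n * n), c(n, n, n))
  expected <- (n - 2) * n * n * 4 / n^3
  expect_equal(bending_energy(ddf(quad, g)), expected, tolerance = 1e-12)
  expect_error(bending_energy(ddf(array(0, c(2, 2, 2, 3)), grid3d(c(2, 2, 2)))), "grid")
})

test_that("bending energy and its gradient match a brute-force oracle", {
  # independent oracle: loop over every voxel and stencil by hand
  brute_be <- function(u) {
    d <- dim(u)[1:3]
    total <- 0
    idx <- function(c, i, j, k) u[i, j, k, c]
    for (c in 1:3) for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (i > 1 && i < d[1])
        total <- total + (idx(c, i + 1, j, k) - 2 * idx(c, i, j, k) + idx(c, i - 1, j, k))^2
      if (j > 1 && j < d[2])
        total <- total + (idx(c, i, j + 1, k) - 2 * idx(c, i, j, k) + idx(c, i, j - 1, k))^2
      if (k > 1 && k < d[3])
        total <- total + (idx(c, i, j, k + 1) - 2 * idx(c, i, j, k) + idx(c, i, j, k - 1))^2
      if (i > 1 && i < d[1] && j > 1 && j < d[2])
        total <- total + 2 * ((idx(c, i + 1, j + 1, k) - idx(c, i + 1, j - 1, k) -
                               idx(c, i - 1, j + 1, k) + idx(c, i - 1, j - 1, k)) / 4)^2
      if (i > 1 && i < d[1] && k > 1 && k < d[3])
        total <- total + 2 * ((idx(c, i + 1, j, k + 1) - idx(c, i + 1, j, k - 1) -
                               idx(c, i - 1, j, k + 1) + idx(c, i - 1, j, k - 1)) / 4)^2
      if (j > 1 && j < d[2] && k > 1 && k < d[3])
        total <- total + 2 * ((idx(c, i, j + 1, k + 1) - idx(c, i, j + 1, k - 1) -
                               idx(c, i, j - 1, k + 1) + idx(c, i, j - 1, k - 1)) / 4)^2
    }
    total / prod(d)
  }
  set.seed(41)
  for (s in 1:3) {
    u <- array(rnorm(5 * 4 * 6 * 3), c(5, 4, 6, 3))
    f <- ddf(u, grid3d(c(5, 4, 6), c(1, 1, 1)))
    expect_equal(bending_energy(f), brute_be(u), tolerance = 1e-12)
  }
  # gradient check by central finite differences at a few entries
  u <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  f <- ddf(u, grid3d(c(4, 4, 4), c(1, 1, 1)))
  gr <- mesoreg:::bending_energy_grad(f)
  h <- 1e-5
  for (t in list(c(2, 2, 2, 1), c(3, 2, 4, 2), c(1, 1, 1, 3), c(4, 3, 2, 1))) {
    up <- u; up[t[1], t[2], t[3], t[4]] <- up[t[1], t[2], t[3], t[4]] + h
    dn <- u; dn[t[1], t[2], t[3], t[4]] <- dn[t[1], t[2], t[3], t[4]] - h
    fd <- (brute_be(up) - brute_be(dn)) / (2 * h)
    expect_equal(gr[t[1], t[2], t[3], t[4]], fd, tolerance = 1e-6)
  }
})

test_that("the total loss decomposes exactly into its three terms", {
  p <- tiny_pair(noise = 0.05, grid = small_grid(c(24, 24, 12)))
  f <- p$fixed$volume
  g <- p$moving$volume
  mf <- p$fixed$mask
  u <- array(0, c(f$grid$shape, 3))
  field <- ddf(u, f$grid)
  # perfectly aligned identical pair with zero field: -1 + 0 + 0
  expect_equal(total_loss(f, f, mf, mf, field), -1, tolerance = 1e-9)
  # decomposition is exact
  gw <- warp_with_ddf(g, field)
  mw <- warp_with_ddf(p$moving$mask, field)
  expect_equal(total_loss(f, gw, mf, mw, field),
               -ncc(f, gw) + gdl_loss(mf, mw) + bending_energy(field),
               tolerance = 1e-12)
  # a misaligned copy scores strictly worse than the aligned original
  shifted <- warp(f, affine_translation(c(80, 40, 0)))
  mshift <- warp(mf, affine_translation(c(80, 40, 0)))
  expect_gt(total_loss(f, shifted, mf, mshift, field), -1)
})

test_that("displacement-field warping matches array shifts and propagates landmarks", {
  p <- tiny_pair(noise = 0.05, grid = small_grid(c(24, 24, 12)))
  v <- p$fixed$volume
  zero <- ddf(array(0, c(v$grid$shape, 3)), v$grid)
  expect_equal(warp_with_ddf(v, zero)$values, v$values, tolerance = 1e-15)
  # constant one-voxel displacement along x = integer array shift
  u1 <- array(0, c(v$grid$shape, 3)); u1[, , , 1] <- 1
  w <- warp_with_ddf(v, ddf(u1, v$grid))
  n1 <- v$grid$shape[1]
  expect_equal(w$values[1:(n1 - 1), , ], v$values[2:n1, , ], tolerance = 1e-12)
  # warping landmarks through the ground-truth smooth field reproduces the
  # recorded moving landmarks to sub-voxel accuracy
  g64 <- grid3d(c(48, 48, 24), c(20, 20, 4))
  gt <- sample_smooth_deformation(g64, 50, 400, seed = 3)
  tree <- generate_vessel_tree(g64, list(depth = 4, branch_prob = 0.9,
                                         radius_range = c(10, 20), tortuosity = 0.2),
                               seed = 6)
  pr <- make_pair(tree, g64, gt, variability = list(dropout_fraction = 0),
                  imaging_params = list(gaussian_noise_sd = 0), seed = 2)
  pred <- transform_points(gt, pr$landmarks_fixed)
  dimnames(pred) <- dimnames(pr$landmarks_fixed)
  expect_lt(tre(pred, pr$landmarks_moving), 0.5 * 20)
  expect_error(warp_with_ddf(v, ddf(array(0, c(10, 10, 10, 3)), grid3d(c(10, 10, 10)))),
               "grid")
})

test_that("the network has the contracted shape, seeded init and near-zero initial field", {
  cfg <- train_config(seed = 7)
  m1 <- build_network(cfg)
  m2 <- build_network(cfg)
  expect_identical(m1$params, m2$params)
  x <- array(rnorm(32 * 32 * 32 * 4), c(32, 32, 32, 4))
  out <- mesoreg:::localnet_forward(m1, x)
  expect_equal(dim(out$ddf), c(32, 32, 32, 3))
  expect_lt(mean(abs(out$ddf)), 0.5)
})

test_that("network backpropagation matches finite-difference parameter gradients", {
  cfg <- train_config(channels = c(2, 3, 4, 4), seed = 3)
  model <- build_network(cfg)
  set.seed(5)
  x <- array(rnorm(16 * 16 * 16 * 4), c(16, 16, 16, 4))
  gout <- array(rnorm(16 * 16 * 16 * 3), c(16, 16, 16, 3))
  fwd <- mesoreg:::localnet_forward(model, x)
  grads <- mesoreg:::localnet_backward(model, fwd$cache, gout)
  loss_of <- function(m) sum(mesoreg:::localnet_forward(m, x)$ddf * gout)
  h <- 1e-6
  for (nm in c("enc1.W", "dec4.W", "head.W", "bn.b")) {
    w <- model$params[[nm]]
    probe <- if (length(w) > 4) sample(length(w), 4) else seq_along(w)
    for (t in probe) {
      mp <- model; mp$params[[nm]][t] <- mp$params[[nm]][t] + h
      mm <- model; mm$params[[nm]][t] <- mm$params[[nm]][t] - h
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * h)
      expect_equal(as.numeric(grads[[nm]][t]), fd, tolerance = 1e-3)
    }
  }
})

test_that("zero-epoch training returns the freshly initialised model", {
  p <- tiny_pair(noise = 0.05, grid = small_grid(c(32, 32, 16)))
  cfg <- train_config(epochs = 0L, seed = 11)
  tr <- train_deformable(list(p), cfg)
  expect_identical(tr$model$params, build_network(cfg)$params)
  expect_length(tr$loss_trace, 0)
})

test_that("a short training run reduces the loss and is seed-reproducible", {
  g <- grid3d(c(32, 32, 16), c(20, 20, 4))
  pairs <- lapply(1:2, function(s) {
    tree <- generate_vessel_tree(g, list(depth = 4, branch_prob = 0.9,
                                         radius_range = c(8, 15), tortuosity = 0.2),
                                 seed = 40 + s)
    gt <- sample_smooth_deformation(g, 40, 300, seed = 50 + s)
    make_pair(tree, g, gt, variability = list(dropout_fraction = 0),
              imaging_params = list(gaussian_noise_sd = 0.05), seed = 60 + s)
  })
  cfg <- train_config(epochs = 8L, seed = 2)
  tr1 <- train_deformable(pairs, cfg)
  expect_lt(tr1$loss_trace[8], tr1$loss_trace[1])
  tr2 <- train_deformable(pairs, cfg)
  expect_identical(tr1$loss_trace, tr2$loss_trace)
  expect_identical(tr1$model$params, tr2$model$params)
})
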