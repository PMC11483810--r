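# Intensity pre-processing chain: high-pass, adaptive Wiener, rolling-ball
# background removal, percentile clipping + slice z-scoring, mask dilation
# and depth-ROI selection.

test_that("depth high-pass removes low frequencies and passes high ones at unit gain", {
  g <- grid3d(c(6, 6, 64), c(20, 20, 4))
  # constant volume is pure DC and maps to (near) zero
  const <- volume3d(array(3.7, g$shape), g)
  expect_lt(max(abs(highpass_filter(const, 0.05)$values)), 1e-10)
  # a sinusoid well above the cutoff passes with gain 1
  zline <- sin(2 * pi * 16 * (0:63) / 64)
  v <- volume3d(array(rep(zline, each = 36), g$shape), g)
  out <- highpass_filter(v, 0.1)  # cutoff at 0.1 x Nyquist = 3.2 cycles/volume
  expect_equal(out$values, v$values, tolerance = 0.01)
  # linearity
  a <- random_volume(c(6, 6, 64), seed = 2)
  lhs <- highpass_filter(volume3d(2.5 * a$values, a$grid), 0.05)$values
  rhs <- 2.5 * highpass_filter(a, 0.05)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # output is mean-free
  expect_lt(abs(mean(highpass_filter(a, 0.05)$values)), 1e-6 * sd(a$values))
  expect_error(highpass_filter(a, 0), "cutoff")
})

test_that("adaptive Wiener filter matches its defining formula slice by slice", {
  # constant slice: zero variance everywhere -> unchanged
  g <- grid3d(c(8, 8, 2), c(20, 20, 4))
  const <- volume3d(array(5, g$shape), g)
  expect_equal(wiener_filter(const)$values, const$values, tolerance = 1e-12)

  # single impulse on a flat background is strictly reduced
  vals <- array(0, c(9, 9, 1))
  vals[5, 5, 1] <- 1
  v <- volume3d(vals, grid3d(c(9, 9, 1)))
  out <- wiener_filter(v)
  expect_lt(out$values[5, 5, 1], 1)
  expect_gt(out$values[5, 5, 1], 0)
  # hand evaluation of the 3x3 formula at the impulse: mu = 1/9,
  # local var = 8/81; nu = mean local variance over the slice
  x <- vals[, , 1]
  mu <- mesoreg:::slice_box_mean(x, 3L)
  lv <- pmax(mesoreg:::slice_box_mean(x * x, 3L) - mu^2, 0)
  nu <- mean(lv)
  expected <- mu[5, 5] + max(lv[5, 5] - nu, 0) / max(lv[5, 5], nu) * (1 - mu[5, 5])
  expect_equal(out$values[5, 5, 1], expected, tolerance = 1e-12)

  # slices are filtered independently: permuting slices commutes
  a <- random_volume(c(7, 7, 4), seed = 3)
  perm <- c(3, 1, 4, 2)
  out1 <- wiener_filter(a)$values[, , perm]
  out2 <- wiener_filter(volume3d(a$values[, , perm], a$grid))$values
  expect_equal(out1, out2, tolerance = 1e-12)
})

test_that("rolling-ball background removal equals the greyscale-opening oracle", {
  # independent oracle: brute-force erosion then dilation with a disk
  brute_opening <- function(x, r) {
    off <- expand.grid(di = -r:r, dj = -r:r)
    off <- off[off$di^2 + off$dj^2 <= r^2, ]
    n1 <- nrow(x); n2 <- ncol(x)
    er <- matrix(Inf, n1, n2)
    for (t in seq_len(nrow(off))) {
      sh <- matrix(Inf, n1, n2)
      i <- seq_len(n1) + off$di[t]; j <- seq_len(n2) + off$dj[t]
      oki <- i >= 1 & i <= n1; okj <- j >= 1 & j <= n2
      sh[oki, okj] <- x[i[oki], j[okj]]
      er <- pmin(er, sh)
    }
    di <- matrix(-Inf, n1, n2)
    for (t in seq_len(nrow(off))) {
      sh <- matrix(-Inf, n1, n2)
      i <- seq_len(n1) - off$di[t]; j <- seq_len(n2) - off$dj[t]
      oki <- i >= 1 & i <= n1; okj <- j >= 1 & j <= n2
      sh[oki, okj] <- er[i[oki], j[okj]]
      di <- pmax(di, sh)
    }
    di
  }
  # constant slice: background equals the slice, residual ~ 0
  g <- grid3d(c(16, 16, 1))
  const <- volume3d(array(2, g$shape), g)
  expect_lt(max(abs(rolling_ball(const, 5)$values)), 1e-9)

  # bright disk smaller than the ball is preserved within 5%
  vals <- array(0.2, c(31, 31, 1))
  ii <- which(outer((1:31) - 16, (1:31) - 16, function(a, b) a^2 + b^2) <= 2^2)
  sl <- vals[, , 1]; sl[ii] <- 1; vals[, , 1] <- sl
  v <- volume3d(vals, grid3d(c(31, 31, 1)))
  out <- rolling_ball(v, 5)
  expect_gt(out$values[16, 16, 1], 0.8 * 0.95)
  # agreement with the oracle on this structured slice and on noise
  bg <- brute_opening(vals[, , 1], 5)
  expect_equal(out$values[, , 1], vals[, , 1] - bg, tolerance = 1e-9)
  rnd <- random_volume(c(20, 20, 2), seed = 9)
  out_r <- rolling_ball(rnd, 3)
  for (k in 1:2)
    expect_equal(out_r$values[, , k],
                 rnd$values[, , k] - brute_opening(rnd$values[, , k], 3),
                 tolerance = 1e-9)

  # a broad linear gradient (scale >> ball) is essentially removed
  gvals <- array(rep(seq(0, 1, length.out = 40), times = 40), c(40, 40, 1))
  gv <- volume3d(gvals, grid3d(c(40, 40, 1)))
  resid <- rolling_ball(gv, 5)$values
  expect_lt(diff(range(resid)), 0.05 * diff(range(gvals)) + 0.15)
})

test_that("clipping and slice z-scoring produce zero-mean unit-sd slices", {
  v <- random_volume(c(12, 12, 6), seed = 4)
  out <- clip_and_zscore(v)
  m <- matrix(out$values, ncol = 6)
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-9)
  # constant slice maps to zero
  vals <- v$values; vals[, , 3] <- 7
  out2 <- clip_and_zscore(volume3d(vals, v$grid))
  expect_true(all(out2$values[, , 3] == 0))
  # extreme values are clipped at the volume-wise percentile cap
  vals2 <- array(rnorm(1000), c(10, 10, 10))
  vals2[1, 1, 1] <- 1e6
  q <- quantile(vals2, 0.9995, names = FALSE)
  clipped <- pmin(pmax(vals2, quantile(vals2, 5e-4, names = FALSE)), q)
  out3 <- clip_and_zscore(volume3d(vals2, grid3d(c(10, 10, 10))))
  ref <- (clipped[, , 1] - mean(clipped[, , 1])) / sd(clipped[, , 1])
  expect_equal(out3$values[, , 1], ref, tolerance = 1e-9)
})

test_that("slice-wise dilation uses a Euclidean disk and only grows masks", {
  g <- grid3d(c(9, 9, 3))
  vals <- array(0, g$shape)
  vals[5, 5, 2] <- 1
  m <- binary_mask(vals, g)
  out <- dilate_mask_slicewise(m, 1)
  # radius-1 disk = centre + 4-neighbourhood, confined to its slice
  expected <- array(0, g$shape)
  expected[5, 5, 2] <- 1; expected[4, 5, 2] <- 1; expected[6, 5, 2] <- 1
  expected[5, 4, 2] <- 1; expected[5, 6, 2] <- 1
  expect_equal(out$values, expected)
  # empty mask stays empty; dilation is extensive and monotone
  empty <- binary_mask(array(0, g$shape), g)
  expect_equal(sum(dilate_mask_slicewise(empty, 2)$values), 0)
  once <- dilate_mask_slicewise(m, 2)
  twice <- dilate_mask_slicewise(once, 2)
  expect_true(all(twice$values >= once$values))
  expect_true(all(once$values >= m$values))
})

test_that("depth-ROI selection crops to the mask's z-range and preserves physical coordinates", {
  g <- grid3d(c(6, 6, 64), c(20, 20, 4))
  vals <- array(0, g$shape)
  vals[3, 3, 10:20] <- 1
  m <- binary_mask(vals, g)
  v <- random_volume(c(6, 6, 64), seed = 5)
  v <- volume3d(v$values, g)
  out <- select_z_roi(v, m)
  expect_equal(out$volume$grid$shape[3], 11L)
  expect_equal(out$volume$grid$origin[3], g$origin[3] + 9 * 4)
  # retained voxels keep their physical z-coordinate and values
  expect_equal(out$volume$values[, , 1], v$values[, , 10])
  # full mask: identity crop
  full <- binary_mask(array(1, g$shape), g)
  expect_equal(select_z_roi(v, full)$volume$grid$shape, g$shape)
  expect_error(select_z_roi(v, binary_mask(array(0, g$shape), g)), "empty")
})

test_that("the chain applies enabled stages in fixed order", {
  v <- random_volume(c(10, 10, 8), seed = 6)
  v <- volume3d(v$values + 2, v$grid)
  cfgw <- preprocess_config(stages = c("wiener", "clip_zscore"))
  ref <- clip_and_zscore(wiener_filter(v, 3L))
  expect_equal(preprocess_volume(v, cfgw)$values, ref$values, tolerance = 1e-12)
  cfg0 <- preprocess_config(stages = character(0))
  expect_identical(preprocess_volume(v, cfg0)$values, v$values)
})
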