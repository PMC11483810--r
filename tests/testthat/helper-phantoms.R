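# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the unit suite stays fast.

small_grid <- function(shape = c(48, 48, 24), spacing = c(20, 20, 4))
  grid3d(shape, spacing)

# A small vessel phantom pair with optional ground-truth transform.
tiny_pair <- function(gt = NULL, dropout = 0, noise = 0, seed = 11,
                      grid = small_grid(), extra = 0) {
  rmax <- min(grid_extent(grid)) / 4          # generator precondition
  rr <- c(0.5, 0.95) * min(rmax, 21)
  tree <- generate_vessel_tree(grid, list(depth = 4, branch_prob = 0.9,
                                          radius_range = rr,
                                          tortuosity = 0.2), seed = seed)
  make_pair(tree, grid, gt,
            variability = list(dropout_fraction = dropout, extra_vessel_count = extra),
            imaging_params = list(depth_decay_per_mm = 0.5, gain = 1,
                                  gaussian_noise_sd = noise,
                                  background_level = if (noise > 0) 0.05 else 0),
            seed = seed + 1L)
}

# Random binary mask with given foreground probability.
random_mask <- function(shape, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  vals <- with_seed2(seed, array(as.numeric(runif(prod(shape)) < p), shape))
  binary_mask(vals, grid3d(shape, spacing))
}

random_volume <- function(shape, seed = 1, spacing = c(1, 1, 1)) {
  vals <- with_seed2(seed, array(rnorm(prod(shape)), shape))
  volume3d(vals, grid3d(shape, spacing))
}

with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Independent O(n^2) oracle: distance from each voxel to the nearest
# foreground voxel of `target` (physical units).
brute_nearest_dist <- function(points, target_points) {
  vapply(seq_len(nrow(points)), function(i) {
    d <- sweep(target_points, 2, points[i, ], `-`)
    sqrt(min(rowSums(d^2)))
  }, numeric(1))
}

# Voxel-centre coordinates (physical) of all foreground voxels of a mask.
fg_coords <- function(m) {
  idx <- which(m$values == 1, arr.ind = TRUE)
  mesoreg:::index_to_physical(m$grid, idx - 1)
}
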