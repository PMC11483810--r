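# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so phantom generation never perturbs
# user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed derivation (Lehmer step), kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

# Shift a 3D array by integer offsets with zero fill.
shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  ix <- sx - dx; iy <- sy - dy; iz <- sz - dz
  okx <- ix >= 1 & ix <= d[1]; oky <- iy >= 1 & iy <= d[2]; okz <- iz >= 1 & iz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[ix[okx], iy[oky], iz[okz]]
  out
}

# Running box sum along one axis of a 3D array (window w centred, truncated
# at the borders), via cumulative sums; returns the per-voxel sum.
box_sum_axis <- function(a, axis, w) {
  half <- (w - 1L) %/% 2L
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  cs <- apply(m, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = d[axis])
  n <- d[axis]
  hi <- pmin(seq_len(n) + half, n)
  lo <- seq_len(n) - half - 1L
  out <- cs[hi, , drop = FALSE]
  pos <- lo >= 1L
  if (any(pos)) out[pos, ] <- out[pos, ] - cs[lo[pos], , drop = FALSE]
  res <- array(out, dim(ap))
  aperm(res, order(perm))
}

# Per-voxel count of in-bounds window elements (same truncation rule).
box_count_axis <- function(n, w) {
  half <- (w - 1L) %/% 2L
  pmin(seq_len(n) + half, n) - pmax(seq_len(n) - half, 1L) + 1L
}

# Truncated-window box mean over a cubic window in 3D.
box_mean3 <- function(a, w) {
  s <- box_sum_axis(box_sum_axis(box_sum_axis(a, 1L, w), 2L, w), 3L, w)
  d <- dim(a)
  cnt <- outer(outer(box_count_axis(d[1], w), box_count_axis(d[2], w)),
               box_count_axis(d[3], w))
  s / cnt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
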