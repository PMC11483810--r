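#' Dense displacement field
#'
#' A per-voxel 3-vector displacement expressed in voxel units of its grid
#' (component c in units of `spacing[c]`). Warping is pull-back:
#' `out(v) = x(v + u(v))`.
#'
#' @param vectors 4D array (nx, ny, nz, 3) of finite voxel-unit displacements.
#' @param grid a [grid3d].
#' @return An object of class `ddf`.
#' @export
ddf <- function(vectors, grid) {
  if (!is.array(vectors) || length(dim(vectors)) != 4 || dim(vectors)[4] != 3)
    stop("ddf: vectors must be an (nx, ny, nz, 3) array")
  if (!all(dim(vectors)[1:3] == grid$shape)) stop("ddf: shape mismatch with grid")
  if (!all(is.finite(vectors))) stop("ddf: all components must be finite")
  structure(list(vectors = vectors, grid = grid), class = "ddf")
}

#' @export
print.ddf <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<ddf> max |u| = %.3f voxels\n", max(mag)))
  print(x$grid)
  invisible(x)
}

# Trilinear sample of a 3D array at continuous 0-based voxel indices
# (n x 3 matrix); zero fill outside.
sample_trilinear <- function(arr, idx) {
  d <- dim(arr)
  n <- nrow(idx)
  out <- numeric(n)
  i0 <- floor(idx)
  fr <- idx - i0
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    ii <- i0[, 1] + di; jj <- i0[, 2] + dj; kk <- i0[, 3] + dk
    w <- (if (di) fr[, 1] else 1 - fr[, 1]) *
         (if (dj) fr[, 2] else 1 - fr[, 2]) *
         (if (dk) fr[, 3] else 1 - fr[, 3])
    ok <- ii >= 0 & jj >= 0 & kk >= 0 & ii < d[1] & jj < d[2] & kk < d[3] & w > 0
    if (any(ok))
      out[ok] <- out[ok] + w[ok] * arr[cbind(ii[ok] + 1, jj[ok] + 1, kk[ok] + 1)]
  }
  out
}

# Physical displacement (um) of a ddf sampled at physical points (n x 3).
ddf_displacement_at <- function(field, pts) {
  pts <- matrix(pts, ncol = 3)
  idx <- physical_to_index(field$grid, pts)
  disp <- sapply(1:3, function(c)
    sample_trilinear(field$vectors[, , , c], idx) * field$grid$spacing[c])
  matrix(disp, ncol = 3)
}

#' Warp a volume or mask through a dense displacement field
#'
#' Pull-back resampling on the field's own grid: `out(v) = x(v + u(v))`,
#' trilinear for volumes, trilinear-then-threshold-0.5 for masks, zero fill
#' outside the grid.
#'
#' @param x a [volume3d] or [binary_mask] on the same grid as `field`.
#' @param field a [ddf].
#' @return Warped object of the same class as `x`.
#' @export
warp_with_ddf <- function(x, field) {
  check_same_grid(x, field)
  vals <- .ddf_warp_cpp(x$values, x$grid$shape, field$vectors, TRUE)
  if (inherits(x, "volume3d")) volume3d(array(vals, x$grid$shape), x$grid)
  else binary_mask(array(as.numeric(vals >= 0.5), x$grid$shape), x$grid)
}

#' Generalised Dice loss
#'
#' Overlap loss between a fixed binary mask and a warped (soft, in \[0,1\])
#' moving mask with two labels (foreground and background) weighted by the
#' inverse squared fixed label volume, counteracting the extreme
#' foreground/background imbalance of sparse vasculature:
#' `GDL = 1 - 2 sum_l w_l sum_i f_li g_li / sum_l w_l sum_i (f_li + g_li)`
#' with `w_l = 1 / (sum_i f_li)^2` (epsilon-guarded). 0 for identical masks.
#'
#' @param mf fixed [binary_mask].
#' @param mg_warped warped moving mask: a [binary_mask] or [volume3d] with
#'   values in \[0, 1\] on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
gdl_loss <- function(mf, mg_warped) {
  check_same_grid(mf, mg_warped)
  g <- mg_warped$values
  if (min(g) < -1e-9 || max(g) > 1 + 1e-9)
    stop("gdl_loss: warped mask values must lie in [0, 1]")
  gdl_terms(mf$values, g)$value
}

# Value and gradient of GDL with respect to the soft moving mask.
gdl_terms <- function(fm, gm) {
  eps <- 1e-8
  f1 <- fm; f0 <- 1 - fm
  g1 <- gm; g0 <- 1 - gm
  w1 <- 1 / (sum(f1) + eps)^2
  w0 <- 1 / (sum(f0) + eps)^2
  num <- w1 * sum(f1 * g1) + w0 * sum(f0 * g0)
  den <- w1 * sum(f1 + g1) + w0 * sum(f0 + g0)
  val <- 1 - 2 * num / den
  dnum <- w1 * f1 - w0 * f0
  dden <- w1 - w0
  grad <- -2 * (dnum * den - num * dden) / den^2
  list(value = val, grad = grad)
}

#' Bending energy of a displacement field
#'
#' Mean over voxels of the squared Frobenius norm of the per-component
#' second-derivative (Hessian) tensor (mixed entries counted twice), with
#' second derivatives by central finite differences in voxel units,
#' evaluated where the stencil support lies inside the grid. Zero for any
#' globally affine field, so minimising it drives deformations towards
#' locally affine behaviour.
#'
#' @param field a [ddf] on a grid with >= 3 voxels per axis.
#' @return Non-negative scalar.
#' @export
bending_energy <- function(field) {
  g <- field$grid
  if (any(g$shape < 3)) stop("bending_energy: grid must be >= 3 voxels per axis")
  .bending_energy_cpp(field$vectors, g$shape, FALSE)$value
}

# Gradient of bending_energy with respect to the field (same 4D shape).
bending_energy_grad <- function(field) {
  array(.bending_energy_cpp(field$vectors, field$grid$shape, TRUE)$grad,
        dim(field$vectors))
}

#' Composite weakly supervised registration loss
#'
#' `L_total = L_img + L_seg + L_BE`: the negative NCC between fixed and
#' warped moving intensities, the generalised Dice loss between fixed and
#' warped moving segmentations, and the bending energy of the displacement
#' field, summed without weights.
#'
#' @param f,g_warped fixed and warped moving [volume3d]s.
#' @param mf fixed [binary_mask].
#' @param mg_warped warped moving (soft) mask.
#' @param field the [ddf] that produced the warps.
#' @return Scalar loss (identical aligned pair with zero field gives -1).
#' @export
total_loss <- function(f, g_warped, mf, mg_warped, field) {
  -ncc(f, g_warped) + gdl_loss(mf, mg_warped) + bending_energy(field)
}

#' Map physical points through an estimated transform
#'
#' Generic landmark propagation into moving space: for an `affine3d` this is
#' the matrix action; for a `ddf` the point is displaced by the field
#' sampled at its position; for a composed deformable result
#' (`ddf_transform`: displacement followed by the rigid pre-alignment) both
#' are applied in order.
#'
#' @param transform an `affine3d`, `ddf` or `ddf_transform`.
#' @param pts n x 3 matrix of physical coordinates (um).
#' @return n x 3 matrix of predicted moving-space coordinates.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  if (inherits(transform, "affine3d")) return(apply_affine(transform, pts))
  if (inherits(transform, "ddf"))
    return(pts + ddf_displacement_at(transform, pts))
  if (inherits(transform, "ddf_transform")) {
    displaced <- pts + ddf_displacement_at(transform$field, pts)
    return(apply_affine(transform$init, displaced))
  }
  stop("transform_points: unsupported transform class")
}
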