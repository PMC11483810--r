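#' Anisotropic 3D sampling grid
#'
#' Defines the geometry of a voxel grid: voxel counts, physical spacing and
#' the physical position of the centre of voxel (0,0,0). All physical
#' coordinates in the package are micrometres; voxel indices are 0-based and
#' refer to voxel centres, so voxel (i,j,k) sits at
#' `origin + (i*dx, j*dy, k*dz)`. The default spacing of 20 x 20 x 4 um
#' matches the native anisotropic sampling of raster-scan photoacoustic
#' mesoscopy reconstructions.
#'
#' @param shape integer vector of 3 voxel counts (nx, ny, nz), all >= 1.
#' @param spacing numeric vector of 3 voxel spacings in micrometres, all > 0.
#' @param origin physical position (um) of the centre of voxel (0,0,0).
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape, spacing = c(20, 20, 4), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("grid3d: all shape entries must be >= 1")
  if (any(spacing <= 0)) stop("grid3d: all spacings must be > 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing (%g, %g, %g) um, origin (%g, %g, %g) um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid geometry helpers
#'
#' `grid_extent` is the physical span between the first and last voxel
#' centres per axis; `grid_centre` the physical centre of the grid (both um).
#' @param grid a [grid3d].
#' @export
grid_extent <- function(grid) (grid$shape - 1L) * grid$spacing

#' @rdname grid_extent
#' @export
grid_centre <- function(grid) grid$origin + grid_extent(grid) / 2

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!grids_equal(a$grid, b$grid))
    stop(sprintf("%s must share the same grid", what))
  invisible(TRUE)
}

#' Scalar intensity volume on a 3D grid
#'
#' @param values 3D numeric array of finite intensities.
#' @param grid a [grid3d]; defaults to unit spacing of 20 x 20 x 4 um at the
#'   origin with the array's dimensions.
#' @param spacing,origin convenience alternatives to `grid`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, grid = NULL, spacing = c(20, 20, 4), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("volume3d: values must be a 3D array")
  if (is.null(grid)) grid <- grid3d(dim(values), spacing, origin)
  if (!all(dim(values) == grid$shape))
    stop("volume3d: values shape does not match grid shape")
  if (!all(is.finite(values))) stop("volume3d: all values must be finite")
  structure(list(values = values, grid = grid), class = "volume3d")
}

#' Binary segmentation mask on a 3D grid
#'
#' @param values 3D array with entries in \{0, 1\} (logical accepted).
#' @inheritParams volume3d
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid = NULL, spacing = c(20, 20, 4), origin = c(0, 0, 0)) {
  if (is.logical(values)) values <- array(as.numeric(values), dim(values))
  if (!is.array(values) || length(dim(values)) != 3)
    stop("binary_mask: values must be a 3D array")
  if (!all(values %in% c(0, 1))) stop("binary_mask: values must be 0 or 1")
  if (is.null(grid)) grid <- grid3d(dim(values), spacing, origin)
  if (!all(dim(values) == grid$shape))
    stop("binary_mask: values shape does not match grid shape")
  structure(list(values = values, grid = grid), class = "binary_mask")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask>", sum(x$values), "foreground voxels\n")
  print(x$grid)
  invisible(x)
}

# Physical coordinates (um) of 0-based voxel indices (n x 3 matrix).
index_to_physical <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

# Continuous 0-based voxel indices of physical points (n x 3, um).
physical_to_index <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`)
}

#' Resample a volume or mask onto a new grid
#'
#' Pull-back resampling: each voxel centre of `grid` is mapped into the input
#' grid and sampled with trilinear (volumes) or nearest-neighbour (masks)
#' interpolation; samples outside the input take the fill value 0.
#'
#' @param x a [volume3d] or [binary_mask].
#' @param grid target [grid3d].
#' @return Object of the same class as `x` on `grid`.
#' @export
resample_to_grid <- function(x, grid) {
  linear <- inherits(x, "volume3d")
  vals <- .resample_affine_cpp(x$values, x$grid$shape, x$grid$origin, x$grid$spacing,
                               grid$shape, grid$origin, grid$spacing,
                               diag(4), linear)
  if (linear) volume3d(vals, grid) else binary_mask(round(vals), grid)
}

#' Resample to isotropic spacing
#'
#' Surface extraction, distance transforms and surface-distance metrics are
#' defined on isotropically sampled grids; this resamples to a cubic voxel,
#' by default at the in-plane spacing (the smaller upsampling error for
#' mesoscopy grids whose z spacing is finer than in-plane).
#'
#' @param x a [volume3d] or [binary_mask].
#' @param target isotropic spacing in um; default `max(spacing[1:2])`.
#' @return Resampled object of the same class.
#' @export
resample_isotropic <- function(x, target = NULL) {
  sp <- x$grid$spacing
  if (is.null(target)) target <- max(sp[1:2])
  if (all(abs(sp - target) < 1e-9)) return(x)
  ext <- grid_extent(x$grid)
  shape <- pmax(1L, as.integer(round(ext / target)) + 1L)
  resample_to_grid(x, grid3d(shape, rep(target, 3), x$grid$origin))
}
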