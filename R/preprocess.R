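#' Pre-processing configuration
#'
#' Parameters of the intensity pre-processing chain applied before
#' registration: high-pass filtering along depth to suppress echo noise,
#' a slice-wise adaptive Wiener filter (3x3 local statistics) against
#' stochastic noise, slice-wise rolling-ball background removal, percentile
#' clipping and slice-wise z-score normalisation to equalise signal across
#' depth. Each stage can be disabled independently.
#'
#' @param highpass_cutoff high-pass cutoff as a fraction of the Nyquist
#'   frequency along z (the filter design is a hard FFT mask; echo noise is
#'   low-frequency along depth).
#' @param wiener_window odd window size (voxels) for local means/variances.
#' @param rolling_ball_radius structuring-disk radius in pixels, per slice.
#' @param clip_percentiles lower/upper clipping percentiles, computed over
#'   the whole volume.
#' @param dilation_radius slice-wise mask dilation radius (pixels).
#' @param stages character vector of enabled stages, in fixed order.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(highpass_cutoff = 0.01, wiener_window = 3L,
                              rolling_ball_radius = 5L,
                              clip_percentiles = c(0.05, 99.95),
                              dilation_radius = 5L,
                              stages = c("highpass", "wiener", "rolling_ball",
                                         "clip_zscore")) {
  stopifnot(rolling_ball_radius >= 1, dilation_radius >= 1,
            wiener_window >= 3, wiener_window %% 2 == 1)
  if (!(clip_percentiles[1] >= 0 && clip_percentiles[1] < clip_percentiles[2] &&
        clip_percentiles[2] <= 100))
    stop("preprocess_config: need 0 <= low percentile < high percentile <= 100")
  structure(list(highpass_cutoff = highpass_cutoff, wiener_window = as.integer(wiener_window),
                 rolling_ball_radius = as.integer(rolling_ball_radius),
                 clip_percentiles = clip_percentiles,
                 dilation_radius = as.integer(dilation_radius), stages = stages),
            class = "preprocess_config")
}

#' High-pass filter along depth
#'
#' Removes low-frequency content (echo noise and the DC level) along the z
#' axis with a hard FFT mask: frequency components below
#' `cutoff * Nyquist` are zeroed independently for every (x, y) line.
#'
#' @param v a [volume3d].
#' @param cutoff fraction of the Nyquist frequency in (0, 1).
#' @return Filtered [volume3d] with (near-)zero mean.
#' @export
highpass_filter <- function(v, cutoff = 0.01) {
  if (!(cutoff > 0 && cutoff < 1)) stop("highpass_filter: cutoff must be in (0, 1)")
  d <- v$grid$shape
  nz <- d[3]
  m <- matrix(aperm(v$values, c(3, 1, 2)), nrow = nz)
  fm <- mvfft(m)
  freq <- pmin(0:(nz - 1), nz - (0:(nz - 1))) / nz  # cycles per sample, Nyquist = 0.5
  kill <- freq < cutoff * 0.5
  fm[kill, ] <- 0
  out <- Re(mvfft(fm, inverse = TRUE)) / nz
  volume3d(aperm(array(out, c(nz, d[1], d[2])), c(2, 3, 1)), v$grid)
}

# Slice-wise box mean with truncated windows at the borders (each pixel
# averages its in-bounds neighbours), so constant slices stay constant.
slice_box_mean <- function(slice, w) {
  half <- (w - 1L) %/% 2L
  n1 <- nrow(slice); n2 <- ncol(slice)
  acc <- matrix(0, n1, n2)
  padded <- matrix(0, n1 + 2 * half, n2 + 2 * half)
  padded[half + seq_len(n1), half + seq_len(n2)] <- slice
  cs <- apply(padded, 2, cumsum)
  cs <- apply(cs, 1, cumsum)  # transposed double cumsum
  cs <- t(cs)
  csp <- matrix(0, nrow(padded) + 1, ncol(padded) + 1)
  csp[-1, -1] <- cs
  for (i in seq_len(n1)) {
    r1 <- i; r2 <- i + 2 * half
    acc[i, ] <- csp[r2 + 1, (seq_len(n2) + 2 * half) + 1] - csp[r1, (seq_len(n2) + 2 * half) + 1] -
                csp[r2 + 1, seq_len(n2)] + csp[r1, seq_len(n2)]
  }
  cnt <- outer(box_count_axis(n1, w), box_count_axis(n2, w))
  acc / cnt
}

#' Adaptive Wiener filter, slice by slice
#'
#' The classical pixel-wise adaptive Wiener filter: within every z slice,
#' local means and variances over a `window x window` neighbourhood
#' (truncated at slice borders) drive
#' `out = mu + max(var - nu, 0) / max(var, nu) * (in - mu)` where `nu` is the
#' slice-mean local variance (the noise-power estimate). Slices are filtered
#' independently; there is no cross-slice leakage.
#'
#' @param v a [volume3d] with every slice at least 3 x 3.
#' @param window odd neighbourhood size (default 3).
#' @return Filtered [volume3d].
#' @export
wiener_filter <- function(v, window = 3L) {
  d <- v$grid$shape
  if (d[1] < window || d[2] < window)
    stop("wiener_filter: each z-slice must be at least window x window")
  out <- v$values
  for (k in seq_len(d[3])) {
    x <- v$values[, , k]
    mu <- slice_box_mean(x, window)
    m2 <- slice_box_mean(x * x, window)
    localvar <- pmax(m2 - mu^2, 0)
    nu <- mean(localvar)
    gain <- if (nu == 0) {
      matrix(0, d[1], d[2])  # constant slice: zero variance everywhere
    } else pmax(localvar - nu, 0) / pmax(localvar, nu)
    out[, , k] <- mu + gain * (x - mu)
  }
  volume3d(out, v$grid)
}

# Euclidean disk structuring element of the given radius (centre included).
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  off <- -r:r
  d2 <- outer(off^2, off^2, `+`)
  matrix(as.numeric(d2 <= radius^2), 2 * r + 1, 2 * r + 1)
}

#' Rolling-ball background removal, slice by slice
#'
#' Estimates the background of every z slice as the greyscale opening
#' (erosion followed by dilation) with a flat disk structuring element of
#' the given radius and subtracts it, homogenising slowly varying background
#' intensity while preserving structures smaller than the disk.
#'
#' @param v a [volume3d].
#' @param radius disk radius in pixels (>= 1).
#' @return Background-subtracted [volume3d].
#' @export
rolling_ball <- function(v, radius = 5L) {
  if (radius < 1) stop("rolling_ball: radius must be >= 1")
  kern <- disk_kernel(radius)
  d <- v$grid$shape
  out <- v$values
  for (k in seq_len(d[3])) {
    x <- v$values[, , k]
    # flat-kernel morphology commutes with constant shifts; EBImage pads
    # borders with zero, so shift so the pad can never win the min (erosion:
    # values <= 0) or the max (dilation: values >= 0)
    hi <- max(x)
    er <- EBImage::erode(x - hi, kern) + hi
    lo <- min(er)
    bg <- EBImage::dilate(er - lo, kern) + lo
    out[, , k] <- x - bg
  }
  volume3d(out, v$grid)
}

#' Percentile clipping and slice-wise z-score normalisation
#'
#' Clips intensities to the given percentile range (computed over the whole
#' volume) and then centres and scales every z slice independently to zero
#' mean and unit standard deviation, so vessels contribute comparable weight
#' across depths despite light-fluence decay. Constant slices map to zero
#' (epsilon-guarded division).
#'
#' @param v a [volume3d].
#' @param percentiles clipping percentiles (volume-wise).
#' @return Normalised [volume3d].
#' @export
clip_and_zscore <- function(v, percentiles = c(0.05, 99.95)) {
  q <- quantile(v$values, percentiles / 100, names = FALSE, type = 7)
  vals <- pmin(pmax(v$values, q[1]), q[2])
  d <- v$grid$shape
  m <- matrix(vals, nrow = d[1] * d[2], ncol = d[3])
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  m <- sweep(m, 2, mu, `-`)
  m <- sweep(m, 2, pmax(sdv, 1e-12), `/`)
  volume3d(array(m, d), v$grid)
}

#' Slice-wise binary mask dilation
#'
#' Dilates every z slice of a segmentation mask with a flat disk footprint
#' (Euclidean disk: radius 1 gives the 4-neighbourhood plus centre), used to
#' build generous intensity ROIs around segmented vessels. The output always
#' contains the input.
#'
#' @param m a [binary_mask].
#' @param radius disk radius in pixels (>= 1).
#' @return Dilated [binary_mask].
#' @export
dilate_mask_slicewise <- function(m, radius = 5L) {
  if (radius < 1) stop("dilate_mask_slicewise: radius must be >= 1")
  kern <- disk_kernel(radius)
  d <- m$grid$shape
  out <- m$values
  for (k in seq_len(d[3])) {
    if (any(m$values[, , k] > 0))
      out[, , k] <- as.numeric(EBImage::dilate(m$values[, , k], kern) > 0)
  }
  binary_mask(array(out, d), m$grid)
}

#' Crop to the z range containing mask signal
#'
#' Restricts both volume and mask to the contiguous range of z slices that
#' carry any mask foreground (the vessel-bearing depth window), updating the
#' grid origin so physical coordinates of retained voxels are unchanged.
#'
#' @param v a [volume3d].
#' @param m a [binary_mask] on the same grid.
#' @return list with cropped `volume` and `mask`.
#' @export
select_z_roi <- function(v, m) {
  check_same_grid(v, m)
  has <- apply(m$values, 3, function(s) any(s > 0))
  if (!any(has)) stop("select_z_roi: mask is empty")
  z0 <- min(which(has)); z1 <- max(which(has))
  g <- v$grid
  newg <- grid3d(c(g$shape[1], g$shape[2], z1 - z0 + 1L), g$spacing,
                 g$origin + c(0, 0, (z0 - 1L) * g$spacing[3]))
  list(volume = volume3d(v$values[, , z0:z1, drop = FALSE], newg),
       mask = binary_mask(m$values[, , z0:z1, drop = FALSE], newg))
}

#' Run the pre-processing chain
#'
#' Applies the enabled stages in the fixed order
#' highpass -> wiener -> rolling_ball -> clip_zscore.
#'
#' @param v a [volume3d].
#' @param config a [preprocess_config].
#' @return Pre-processed [volume3d].
#' @export
preprocess_volume <- function(v, config = preprocess_config()) {
  st <- config$stages
  if ("highpass" %in% st) v <- highpass_filter(v, config$highpass_cutoff)
  if ("wiener" %in% st) v <- wiener_filter(v, config$wiener_window)
  if ("rolling_ball" %in% st) v <- rolling_ball(v, config$rolling_ball_radius)
  if ("clip_zscore" %in% st) v <- clip_and_zscore(v, config$clip_percentiles)
  v
}
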