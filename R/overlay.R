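#' Overlay rendering specification
#'
#' Maximum-intensity-projection overlays follow the standard mesoscopy
#' colour convention: magenta for mismatched fixed-image signal, green for
#' mismatched moving-image signal, white where both coincide.
#'
#' @param axis projection axis, one of "x", "y", "z" (default "z").
#' @param percentile per-channel intensity scaling percentile (default 99.9).
#' @export
overlay_spec <- function(axis = c("z", "x", "y"), percentile = 99.9) {
  axis <- match.arg(axis)
  structure(list(axis = axis, percentile = percentile), class = "overlay_spec")
}

#' Magenta/green MIP overlay of a registered pair
#'
#' Projects both volumes by per-pixel maximum along the chosen axis, scales
#' each projection by its own upper-percentile intensity, and merges them
#' into an RGB image with the fixed image on the magenta (R+B) channels and
#' the moving image on the green channel, so matched signal renders
#' white/grey.
#'
#' @param f fixed [volume3d].
#' @param g_warped warped moving [volume3d] on the same grid.
#' @param spec an [overlay_spec].
#' @return An `H x W x 3` RGB array in \[0, 1\] (the two non-projected axes).
#' @export
render_mip_overlay <- function(f, g_warped, spec = overlay_spec()) {
  check_same_grid(f, g_warped)
  ax <- match(spec$axis, c("x", "y", "z"))
  keep <- setdiff(1:3, ax)
  mip <- function(v) apply(v$values, keep, max)
  scale01 <- function(m, pct) {
    lo <- min(m)
    hi <- quantile(m, pct / 100, names = FALSE)
    if (hi <= lo) hi <- lo + 1
    pmin(pmax((m - lo) / (hi - lo), 0), 1)
  }
  fm <- scale01(mip(f), spec$percentile)
  gm <- scale01(mip(g_warped), spec$percentile)
  out <- array(0, c(dim(fm), 3))
  out[, , 1] <- fm  # red
  out[, , 2] <- gm  # green
  out[, , 3] <- fm  # blue -> fixed shows magenta, overlap white
  out
}

#' Save an overlay to PNG
#'
#' @param overlay RGB array from [render_mip_overlay].
#' @param path output PNG path.
#' @export
save_overlay_png <- function(overlay, path) {
  grDevices::png(path, width = dim(overlay)[2], height = dim(overlay)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(aperm(overlay, c(2, 1, 3)), 0, 0, 1, 1)
  invisible(path)
}
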