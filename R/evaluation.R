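#' Dice coefficient between two masks
#'
#' `2 |G intersect F| / (|G| + |F|)` over voxel counts.
#'
#' @param g,f [binary_mask]s on the same grid, not both empty.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(g, f) {
  check_same_grid(g, f)
  ng <- sum(g$values); nf <- sum(f$values)
  if (ng + nf == 0) stop("dice: both masks are empty")
  2 * sum(g$values * f$values) / (ng + nf)
}

# Border voxels (6-connectivity against background), as a 0/1 array.
surface_voxels <- function(a) {
  interior <- shift3(a, 1, 0, 0) * shift3(a, -1, 0, 0) *
              shift3(a, 0, 1, 0) * shift3(a, 0, -1, 0) *
              shift3(a, 0, 0, 1) * shift3(a, 0, 0, -1)
  a * (1 - interior)
}

#' Symmetric surface distances between two masks
#'
#' Surfaces are the foreground voxels adjacent (6-connectivity) to
#' background, taken on the isotropically resampled grid; distances are
#' physical (um) to the nearest voxel of the other surface, computed with
#' the exact Euclidean distance transform. `md` is the symmetric average
#' surface distance (the two directed sums divided by the total surface
#' voxel count); `hd` is the symmetric Hausdorff distance (max of the two
#' directed maxima).
#'
#' @param g,f non-empty [binary_mask]s on the same grid.
#' @return list with `md` and `hd` (um).
#' @export
surface_distances <- function(g, f) {
  check_same_grid(g, f)
  if (sum(g$values) == 0 || sum(f$values) == 0)
    stop("surface_distances: empty mask")
  g <- resample_isotropic(g); f <- resample_isotropic(f)
  sp <- g$grid$spacing
  sg <- surface_voxels(g$values)
  sf <- surface_voxels(f$values)
  # distance of every voxel to the nearest surface voxel of the other mask:
  # EDT of the complement (zeros exactly on the surface set)
  d_to_f <- .edt_cpp(1 - sf, g$grid$shape, sp)
  d_to_g <- .edt_cpp(1 - sg, g$grid$shape, sp)
  dg <- d_to_f[sg == 1]   # directed distances G_s -> F_s
  df <- d_to_g[sf == 1]
  list(md = (sum(dg) + sum(df)) / (length(dg) + length(df)),
       hd = max(max(dg), max(df)))
}

#' Structural similarity index between two volumes
#'
#' Two-term SSIM map from local means, standard deviations and
#' cross-covariance over a cubic moving window (truncated at borders),
#' averaged over all voxels:
#' `((2 mu_f mu_g + C1)(2 sigma_fg + C2)) / ((mu_f^2 + mu_g^2 + C1)(sigma_f^2 + sigma_g^2 + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` and `L` the dynamic range of
#' the fixed volume. Passing `window = NULL` uses global statistics (one
#' window spanning the whole volume).
#'
#' @param f,g [volume3d]s on the same grid.
#' @param window odd cubic window size in voxels (default 7), or NULL.
#' @return Scalar SSIM (1 for identical volumes).
#' @export
ssim <- function(f, g, window = 7L) {
  check_same_grid(f, g)
  L <- diff(range(f$values))
  if (L == 0) L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  fv <- f$values; gv <- g$values
  if (is.null(window)) {
    muf <- mean(fv); mug <- mean(gv)
    vf <- mean((fv - muf)^2); vg <- mean((gv - mug)^2)
    cov <- mean((fv - muf) * (gv - mug))
    return(((2 * muf * mug + C1) * (2 * cov + C2)) /
           ((muf^2 + mug^2 + C1) * (vf + vg + C2)))
  }
  muf <- box_mean3(fv, window); mug <- box_mean3(gv, window)
  vf <- pmax(box_mean3(fv * fv, window) - muf^2, 0)
  vg <- pmax(box_mean3(gv * gv, window) - mug^2, 0)
  cov <- box_mean3(fv * gv, window) - muf * mug
  m <- ((2 * muf * mug + C1) * (2 * cov + C2)) /
       ((muf^2 + mug^2 + C1) * (vf + vg + C2))
  mean(m)
}

#' Target registration error
#'
#' Mean Euclidean distance (um) between paired landmarks sharing labels.
#'
#' @param lf,lg_warped labelled n x 3 matrices (rownames = labels) with at
#'   least one shared label.
#' @return Mean distance in um.
#' @export
tre <- function(lf, lg_warped) {
  shared <- intersect(rownames(lf), rownames(lg_warped))
  if (length(shared) == 0) stop("tre: no shared landmark labels")
  d <- lf[shared, , drop = FALSE] - lg_warped[shared, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Percent change of a quality metric
#'
#' `100 * (post - pre) / |pre|`; positive values mean the metric increased
#' (an improvement for Dice/MI/SSIM, a worsening for surface distances and
#' TRE).
#'
#' @param pre,post metric values before/after registration; `pre != 0`.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("percent_change: pre-registration value is zero")
  100 * (post - pre) / abs(pre)
}

#' Evaluate registration quality for one pair and method
#'
#' Computes the full pre/post metric panel for a registered pair: Dice,
#' symmetric surface distances (um), mutual information (nats), SSIM on
#' intensities, and landmark TRE (um, via [transform_points]); percent
#' changes follow [percent_change].
#'
#' @param fixed list with `volume` and `mask`.
#' @param moving list with `volume` and `mask` (pre-registration state).
#' @param warped list with `volume` and `mask` (post-registration state, on
#'   the fixed grid).
#' @param transform estimated transform for landmark propagation (or NULL
#'   to skip TRE).
#' @param landmarks_fixed,landmarks_moving labelled landmark matrices.
#' @param method,pair_id identifiers copied into the report.
#' @return A tibble with one row per metric: pre, post, percent change.
#' @export
evaluate_pair <- function(fixed, moving, warped, transform = NULL,
                          landmarks_fixed = NULL, landmarks_moving = NULL,
                          method = "method", pair_id = "pair") {
  rows <- list()
  add <- function(metric, pre, post)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      pair_id = pair_id, method = method, metric = metric,
      pre = pre, post = post,
      # a zero pre-registration value (e.g. fully disjoint masks) leaves the
      # relative change undefined
      pct_change = if (pre == 0) NA_real_ else percent_change(pre, post))
  add("dice", dice(moving$mask, fixed$mask), dice(warped$mask, fixed$mask))
  sd_pre <- surface_distances(moving$mask, fixed$mask)
  sd_post <- surface_distances(warped$mask, fixed$mask)
  add("md", sd_pre$md, sd_post$md)
  add("hd", sd_pre$hd, sd_post$hd)
  add("mi", mutual_information(fixed$volume, moving$volume),
      mutual_information(fixed$volume, warped$volume))
  add("ssim", ssim(fixed$volume, moving$volume), ssim(fixed$volume, warped$volume))
  if (!is.null(transform) && !is.null(landmarks_fixed) && !is.null(landmarks_moving)) {
    pre_tre <- tre(landmarks_fixed, landmarks_moving)
    pred <- transform_points(transform, landmarks_fixed)
    dimnames(pred) <- dimnames(landmarks_fixed)
    add("tre", pre_tre, tre(pred, landmarks_moving))
  }
  do.call(rbind, rows)
}
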