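#' Similarity metric specification
#'
#' @param kind `"ncc"` (normalised cross-correlation) or `"mi"` (mutual
#'   information from binned intensity histograms).
#' @param histogram_bins number of equal-width bins per image for MI (>= 2).
#' @export
similarity_metric <- function(kind = c("ncc", "mi"), histogram_bins = 50L) {
  kind <- match.arg(kind)
  if (histogram_bins < 2) stop("similarity_metric: bins must be >= 2")
  structure(list(kind = kind, histogram_bins = as.integer(histogram_bins)),
            class = "similarity_metric")
}

#' Gradient-ascent optimiser settings
#'
#' @param learning_rate initial step length in the scaled parameter space
#'   (step-halving line search guards divergence; the step is never grown).
#' @param max_iterations iteration cap (default 100).
#' @param convergence_min stop when the iteration-to-iteration metric change
#'   falls below this (default 1e-8).
#' @param dof `"rigid"` (6 parameters) or `"affine"` (12 parameters).
#' @param sampling_stride metric evaluations during optimisation run on the
#'   fixed grid subsampled by this integer stride per axis (1 = every voxel);
#'   the returned warped image always uses the full grid.
#' @export
optimizer_settings <- function(learning_rate = 1, max_iterations = 100L,
                               convergence_min = 1e-8,
                               dof = c("rigid", "affine"),
                               sampling_stride = 2L) {
  dof <- match.arg(dof)
  stopifnot(learning_rate > 0, max_iterations >= 1)
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 convergence_min = convergence_min, dof = dof,
                 sampling_stride = as.integer(sampling_stride)),
            class = "optimizer_settings")
}

# Equal-width bin indices over an image's own intensity range.
bin_indices <- function(x, bins) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rep(1L, length(x)))
  idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(idx, bins)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between two volumes
#'
#' `MI = H(F) + H(G) - H(F, G)` in nats, from the joint 2D histogram of
#' co-located voxel intensities with `bins` equal-width bins per image over
#' each image's own range; zero-probability bins contribute nothing.
#'
#' @param f,g [volume3d]s on the same grid.
#' @param bins histogram bins per image (>= 2).
#' @return MI in nats (non-negative, bounded by min of the marginal entropies).
#' @export
mutual_information <- function(f, g, bins = 50L) {
  check_same_grid(f, g)
  if (bins < 2) stop("mutual_information: bins must be >= 2")
  fi <- bin_indices(as.numeric(f$values), bins)
  gi <- bin_indices(as.numeric(g$values), bins)
  joint <- tabulate(fi + bins * (gi - 1L), nbins = bins * bins)
  n <- length(fi)
  pj <- joint / n
  pf <- rowSums(matrix(pj, bins, bins))
  pg <- colSums(matrix(pj, bins, bins))
  entropy_nats(pf) + entropy_nats(pg) - entropy_nats(pj)
}

#' Normalised cross-correlation between two volumes
#'
#' The centred voxel-wise dot product divided by the product of the centred
#' L2 norms, in \[-1, 1\]; invariant to positive affine intensity rescaling.
#'
#' @param f,g [volume3d]s on the same grid, neither constant.
#' @export
ncc <- function(f, g) {
  check_same_grid(f, g)
  fv <- as.numeric(f$values); gv <- as.numeric(g$values)
  fc <- fv - mean(fv); gc <- gv - mean(gv)
  nf <- sqrt(sum(fc^2)); ng <- sqrt(sum(gc^2))
  if (nf == 0 || ng == 0) stop("ncc: constant input (zero denominator)")
  sum(fc * gc) / (nf * ng)
}

# Intensity centroid in physical coordinates (negatives floored to zero).
intensity_centroid <- function(v) {
  w <- pmax(v$values, 0)
  tot <- sum(w)
  if (tot <= 0) stop("com_initialize: volume has zero mass")
  d <- v$grid$shape
  wx <- apply(w, 1, sum); wy <- apply(w, 2, sum); wz <- apply(w, 3, sum)
  idx <- c(sum(wx * (0:(d[1] - 1))), sum(wy * (0:(d[2] - 1))), sum(wz * (0:(d[3] - 1)))) / tot
  v$grid$origin + idx * v$grid$spacing
}

#' Centre-of-mass initialisation
#'
#' Pure translation mapping the intensity centroid of the fixed volume onto
#' the moving volume's centroid (negative intensities are floored to zero
#' for the mass computation).
#'
#' @param f,g fixed and moving [volume3d]s.
#' @return An `affine3d` translation (fixed -> moving convention).
#' @export
com_initialize <- function(f, g) {
  cf <- intensity_centroid(f)
  cg <- intensity_centroid(g)
  affine_translation(cg - cf)
}

#' Landmark-based rigid initialisation
#'
#' Least-squares rigid alignment (Kabsch) of paired labelled landmarks:
#' returns the rotation + translation (det = +1) minimising
#' `sum ||T(lf) - lg||^2` over shared labels.
#'
#' @param lf,lg labelled landmark matrices (n x 3, rownames = labels, um)
#'   with at least 3 shared, non-collinear labels.
#' @return An `affine3d` (fixed -> moving convention).
#' @export
landmark_initialize <- function(lf, lg) {
  shared <- intersect(rownames(lf), rownames(lg))
  if (length(shared) < 3) stop("landmark_initialize: need >= 3 shared landmarks")
  P <- lf[shared, , drop = FALSE]
  Q <- lg[shared, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  sv <- svd(t(P0) %*% Q0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("landmark_initialize: landmarks are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- qc - R %*% pc
  affine3d(m)
}

#' Warp a volume or mask through an affine transform
#'
#' Pull-back resampling onto `grid` (default: the input's own grid): the
#' output at fixed-grid voxel centre `v` is the input sampled at `t(v)`,
#' with trilinear interpolation for volumes, nearest neighbour for masks,
#' and fill value 0 outside.
#'
#' @param x a [volume3d] or [binary_mask] (the moving image).
#' @param t an `affine3d` mapping fixed to moving physical coordinates.
#' @param grid output [grid3d] (the fixed grid); default `x$grid`.
#' @return Warped object of the same class as `x`.
#' @export
warp <- function(x, t, grid = NULL) {
  if (abs(det(t$matrix[1:3, 1:3])) < 1e-12) stop("warp: singular transform")
  if (is.null(grid)) grid <- x$grid
  linear <- inherits(x, "volume3d")
  vals <- .resample_affine_cpp(x$values, x$grid$shape, x$grid$origin, x$grid$spacing,
                               grid$shape, grid$origin, grid$spacing, t$matrix, linear)
  if (linear) volume3d(vals, grid) else binary_mask(array(vals, grid$shape), grid)
}

# Subsampled copy of a grid for fast metric evaluation during optimisation.
strided_grid <- function(grid, stride) {
  if (stride <= 1L) return(grid)
  shape <- pmax(1L, (grid$shape + stride - 1L) %/% stride)
  grid3d(shape, grid$spacing * stride, grid$origin)
}

# Metric value for moving volume g pulled through transform onto eval grid
# (fused warp + metric accumulation in C; f statistics precomputed).
eval_metric <- function(fv_eval, f_bins, g, g_range, transform, eval_grid, metric) {
  .metric_affine_cpp(fv_eval, f_bins, g$values, g$grid$shape, g$grid$origin,
                     g$grid$spacing, eval_grid$shape, eval_grid$origin,
                     eval_grid$spacing, transform$matrix,
                     if (metric$kind == "ncc") 0L else 1L,
                     metric$histogram_bins %||% 50L, g_range[1], g_range[2])
}

# Build the parameterised incremental transform about the fixed-grid centre.
param_transform <- function(alpha, dof, centre) {
  if (dof == "rigid") {
    affine_rigid(rotation = alpha[4:6], translation = alpha[1:3], center = centre)
  } else {
    A <- diag(3) + matrix(alpha[4:12], 3, 3)
    affine_linear(A, translation = alpha[1:3], center = centre)
  }
}

#' Affine registration by gradient ascent on an intensity metric
#'
#' Maximises the chosen similarity metric between the fixed volume and the
#' warped moving volume over a rigid (6-parameter) or full affine
#' (12-parameter) transform composed with the initial transform. The
#' gradient is taken by central finite differences (steps: 1 um translation,
#' 0.001 rad rotation / 0.001 linear-block entries) in a scaled parameter
#' space; each iteration steps along the normalised scaled gradient with a
#' step-halving line search that only ever shrinks the step. Iteration stops
#' at `max_iterations`, when the metric change falls below
#' `convergence_min`, or when the line search collapses. The best transform
#' visited is returned.
#'
#' @param f fixed [volume3d].
#' @param g moving [volume3d].
#' @param metric a [similarity_metric].
#' @param init initial `affine3d` (fixed -> moving); default
#'   centre-of-mass initialisation.
#' @param opts an [optimizer_settings].
#' @return A `registration_result`: `transform` (fixed -> moving),
#'   `metric_trace` (metric value per accepted iteration), `iterations`,
#'   `converged`, `warped` (moving volume warped onto the fixed grid).
#' @export
register_affine <- function(f, g, metric = similarity_metric("ncc"),
                            init = NULL, opts = optimizer_settings()) {
  if (is.null(init)) init <- com_initialize(f, g)
  if (abs(det(init$matrix[1:3, 1:3])) < 1e-12)
    stop("register_affine: degenerate initial transform")
  centre <- grid_centre(f$grid)
  eval_grid <- strided_grid(f$grid, opts$sampling_stride)
  fv_eval <- as.numeric(
    .resample_affine_cpp(f$values, f$grid$shape, f$grid$origin, f$grid$spacing,
                         eval_grid$shape, eval_grid$origin, eval_grid$spacing,
                         diag(4), TRUE))
  f_bins <- bin_indices(fv_eval, metric$histogram_bins %||% 50L)

  np <- if (opts$dof == "rigid") 6L else 12L
  # finite-difference probe steps: NCC is smooth at micrometre scale, but
  # histogram MI carries sub-voxel resampling ripple, so its gradient is
  # probed at half-voxel scale
  fd_step <- if (metric$kind == "mi") c(rep(10, 3), rep(0.01, np - 3L))
             else c(rep(1, 3), rep(1e-3, np - 3L))
  scale <- c(rep(50, 3), rep(0.05, np - 3L))           # parameter scaling
  alpha <- rep(0, np)

  g_range <- range(g$values)
  psi_of <- function(a)
    eval_metric(fv_eval, f_bins, g, g_range,
                compose_affine(init, param_transform(a, opts$dof, centre)),
                eval_grid, metric)

  psi <- psi_of(alpha)
  psi0 <- psi
  best <- list(alpha = alpha, psi = psi)
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (n in seq_len(opts$max_iterations)) {
    grad <- vapply(seq_len(np), function(k) {
      ap <- alpha; am <- alpha
      ap[k] <- ap[k] + fd_step[k]; am[k] <- am[k] - fd_step[k]
      (psi_of(ap) - psi_of(am)) / (2 * fd_step[k])
    }, numeric(1))
    sg <- grad * scale
    gn <- sqrt(sum(sg^2))
    if (gn == 0) { converged <- TRUE; break }
    dir <- sg / gn
    # backtracking line search: start each iteration from the preset
    # learning rate and only ever halve (guards divergence); a fully failed
    # search means no ascent direction at this resolution, i.e. convergence
    accepted <- FALSE
    step <- opts$learning_rate
    for (h in 1:14) {
      cand <- alpha + step * scale * dir
      psi_c <- psi_of(cand)
      if (psi_c > psi) { alpha <- cand; psi_new <- psi_c; accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    iters <- n
    trace <- c(trace, psi_new)
    if (psi_new > best$psi) best <- list(alpha = alpha, psi = psi_new)
    if (abs(psi_new - psi) < opts$convergence_min) { psi <- psi_new; converged <- TRUE; break }
    psi <- psi_new
  }
  transform <- compose_affine(init, param_transform(best$alpha, opts$dof, centre))
  structure(list(transform = transform, metric_trace = trace, iterations = iters,
                 converged = converged, metric = metric$kind,
                 initial_value = psi0, final_value = best$psi,
                 warped = warp(g, transform, grid = f$grid)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s: %d iterations, %s, final value %.6g\n",
              x$metric %||% "?", x$iterations,
              if (isTRUE(x$converged)) "converged" else "iteration cap",
              x$final_value))
  invisible(x)
}
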