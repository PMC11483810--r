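#' Generate a random branching vessel tree
#'
#' Grows a random binary branching tree of straight tubular segments inside
#' the physical domain of `domain`. The geometry emulates the sparse,
#' predominantly in-plane vascular networks seen in mesoscopic photoacoustic
#' scans of skin and superficial tumours: segments run mostly parallel to the
#' imaging plane inside a thin slab, radii taper towards the periphery, and
#' bifurcations create branch points usable as registration landmarks. No
#' haemodynamic realism is attempted; the tree is a geometric scaffold for
#' registration benchmarking.
#'
#' @param domain a [grid3d] defining the physical domain.
#' @param branching_params list with `depth` (generations, >= 1),
#'   `branch_prob` (probability a node bifurcates), `radius_range`
#'   (c(min, max) segment radii, um) and `tortuosity` (0-1, direction jitter).
#' @param seed integer seed; the same seed reproduces the tree exactly.
#' @return An object of class `vessel_tree`: a segment table (physical
#'   endpoint coordinates and radii, um), parent links, and the branch-point
#'   coordinates.
#' @export
generate_vessel_tree <- function(domain,
                                 branching_params = list(depth = 5, branch_prob = 0.8,
                                                         radius_range = c(25, 60),
                                                         tortuosity = 0.2),
                                 seed = 1L) {
  bp <- branching_params
  depth <- bp$depth %||% 5L
  branch_prob <- bp$branch_prob %||% 0.8
  rr <- bp$radius_range %||% c(25, 60)
  tort <- bp$tortuosity %||% 0.2
  if (depth < 1) stop("generate_vessel_tree: depth must be >= 1")
  if (rr[1] > rr[2]) stop("generate_vessel_tree: radius_range is inverted")
  ext <- grid_extent(domain)
  if (any(ext <= 0) && depth > 0) {
    if (all(domain$shape == 1L)) stop("generate_vessel_tree: empty domain")
  }
  if (rr[2] <= 0 || rr[2] > min(ext[ext > 0]) / 4)
    stop("generate_vessel_tree: radius_range must lie within (0, min domain extent/4]")

  # a registration-benchmark tree must carry landmarkable bifurcations;
  # redraw (deterministically) if the branching randomness yields too few
  min_bp <- if (depth >= 3) 3L else if (depth >= 2) 1L else 0L
  for (attempt in 0:19) {
    tree <- vessel_tree_draw(domain, depth, branch_prob, rr, tort,
                             if (attempt == 0) seed else derive_seed(seed, 7000L + attempt))
    if (nrow(tree_branch_points(tree)) >= min_bp) return(tree)
  }
  stop("generate_vessel_tree: could not draw a tree with enough branch points")
}

vessel_tree_draw <- function(domain, depth, branch_prob, rr, tort, seed) {
  ext <- grid_extent(domain)
  o <- domain$origin
  margin <- rr[2]
  lo <- o + pmin(margin, ext / 4)
  hi <- o + ext - pmin(margin, ext / 4)
  mid_z <- o[3] + ext[3] / 2
  seg_len0 <- 0.28 * min(ext[1], ext[2])

  with_seed(seed, {
    segs <- list()
    # queue entries: start point, in-plane heading (rad), z-slope, radius, gen, parent id
    start <- c(lo[1], o[2] + ext[2] * runif(1, 0.35, 0.65), mid_z + ext[3] * runif(1, -0.1, 0.1))
    queue <- list(list(p = start, theta = runif(1, -0.3, 0.3), zs = runif(1, -0.1, 0.1),
                       r = runif(1, 0.7, 1) * rr[2], gen = 1L, parent = 0L))
    nid <- 0L
    while (length(queue) > 0) {
      node <- queue[[1]]; queue <- queue[-1]
      nid <- nid + 1L
      len <- seg_len0 * 0.85^(node$gen - 1) * runif(1, 0.75, 1.1)
      dir <- c(cos(node$theta), sin(node$theta), node$zs)
      dir <- dir / sqrt(sum(dir^2))
      q <- node$p + len * dir
      q <- pmin(pmax(q, lo), hi)
      segs[[nid]] <- list(id = nid, parent = node$parent, gen = node$gen,
                          p0 = node$p, p1 = q, r = node$r)
      if (node$gen < depth) {
        nchild <- if (runif(1) < branch_prob) 2L else 1L
        if (nchild == 2L) {
          split <- runif(1, 0.35, 0.8)
          for (sgn in c(-1, 1)) {
            th <- node$theta + sgn * split + tort * runif(1, -0.5, 0.5)
            zs <- node$zs + tort * runif(1, -0.25, 0.25)
            r <- max(rr[1], node$r * runif(1, 0.65, 0.85))
            queue <- c(queue, list(list(p = q, theta = th, zs = zs, r = r,
                                        gen = node$gen + 1L, parent = nid)))
          }
        } else {
          th <- node$theta + tort * runif(1, -1, 1)
          zs <- node$zs + tort * runif(1, -0.25, 0.25)
          r <- max(rr[1], node$r * runif(1, 0.8, 0.95))
          queue <- c(queue, list(list(p = q, theta = th, zs = zs, r = r,
                                      gen = node$gen + 1L, parent = nid)))
        }
      }
    }
    seg_df <- do.call(rbind, lapply(segs, function(s)
      data.frame(id = s$id, parent = s$parent, gen = s$gen,
                 x0 = s$p0[1], y0 = s$p0[2], z0 = s$p0[3],
                 x1 = s$p1[1], y1 = s$p1[2], z1 = s$p1[3], radius = s$r)))
    tree <- structure(list(segments = seg_df, domain = domain), class = "vessel_tree")
    tree
  })
}

# Number of children per segment id.
tree_child_counts <- function(tree) {
  tab <- table(factor(tree$segments$parent, levels = tree$segments$id))
  as.integer(tab)
}

#' Branch points of a vessel tree
#'
#' A branch point is the end point of a segment from which at least two
#' child segments emanate.
#' @param tree a `vessel_tree`.
#' @return n x 3 matrix of physical coordinates (um), rownames = segment ids.
#' @export
tree_branch_points <- function(tree) {
  nch <- tree_child_counts(tree)
  idx <- which(nch >= 2L)
  if (length(idx) == 0)
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  s <- tree$segments[idx, ]
  m <- as.matrix(s[, c("x1", "y1", "z1")])
  dimnames(m) <- list(paste0("bp", s$id), c("x", "y", "z"))
  m
}

# Terminal (childless) segment ids.
tree_terminals <- function(tree) tree$segments$id[tree_child_counts(tree) == 0L]

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments, %d branch points, radii [%.1f, %.1f] um\n",
              nrow(x$segments), nrow(tree_branch_points(x)),
              min(x$segments$radius), max(x$segments$radius)))
  invisible(x)
}

#' Rasterise a vessel tree onto a grid
#'
#' A voxel belongs to the mask iff its centre lies within the segment radius
#' of some segment axis (physical point-to-segment distance). The intensity
#' volume equals 1 inside the tube with a linear soft edge decaying to 0 over
#' one voxel (the largest spacing) beyond the radius, so tubes are not
#' aliased to hard steps.
#'
#' @param tree a `vessel_tree`.
#' @param grid target [grid3d].
#' @return list with elements `volume` ([volume3d]) and `mask` ([binary_mask]).
#' @export
rasterize_tree <- function(tree, grid) {
  if (nrow(tree$segments) == 0) stop("rasterize_tree: tree is empty")
  segm <- as.matrix(tree$segments[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius")])
  res <- .rasterize_cpp(segm, grid$shape, grid$origin, grid$spacing)
  list(volume = volume3d(res$volume, grid),
       mask = binary_mask(array(as.numeric(res$mask), grid$shape), grid))
}

#' Apply the mesoscopy imaging model to a clean volume
#'
#' Emulates the main intensity confounds of depth-resolved photoacoustic
#' mesoscopy: exponential light-fluence decay with depth, scan-to-scan gain,
#' a constant background offset, and additive Gaussian noise. The expected
#' value at a voxel is `background + gain * clean * exp(-decay * z_mm)`
#' where `z_mm` is the depth below the first slice.
#'
#' @param clean a [volume3d] of noiseless intensities.
#' @param params list with `depth_decay_per_mm` (>= 0), `gain` (> 0),
#'   `gaussian_noise_sd` (>= 0) and `background_level`.
#' @param seed integer seed for the noise.
#' @return A [volume3d].
#' @export
apply_imaging_model <- function(clean,
                                params = list(depth_decay_per_mm = 0.5, gain = 1,
                                              gaussian_noise_sd = 0.1,
                                              background_level = 0.05),
                                seed = 1L) {
  decay <- params$depth_decay_per_mm %||% 0.5
  gain <- params$gain %||% 1
  sd_n <- params$gaussian_noise_sd %||% 0.1
  bg <- params$background_level %||% 0.05
  if (decay < 0) stop("apply_imaging_model: negative depth decay rejected")
  if (gain <= 0) stop("apply_imaging_model: gain must be > 0")
  if (sd_n < 0) stop("apply_imaging_model: noise sd must be >= 0")
  g <- clean$grid
  z_mm <- (seq_len(g$shape[3]) - 1L) * g$spacing[3] / 1000
  atten <- exp(-decay * z_mm)
  vals <- sweep(clean$values * gain, 3, atten, `*`) + bg
  if (sd_n > 0)
    vals <- vals + with_seed(seed, array(rnorm(length(vals), 0, sd_n), dim(vals)))
  volume3d(vals, g)
}

#' Sample a random rigid transform
#'
#' Draws a rigid transform (rotation about `center` composed with a
#' translation) with rotation angle at most `max_rotation_rad` (uniform over
#' a uniformly random axis) and translation magnitude at most
#' `max_translation_um` (uniform direction and magnitude).
#'
#' @param max_translation_um non-negative translation bound: a single
#'   magnitude bound, or a length-3 vector of per-axis bounds (repositioned
#'   mesoscopy scans move mostly in-plane, so a thin slab calls for a small
#'   z bound to keep the anatomy inside the depth window).
#' @param max_rotation_rad non-negative rotation-angle bound.
#' @param seed integer seed.
#' @param center rotation pivot (um); pass the grid centre so sampled
#'   rotations stay within the field of view.
#' @return An `affine3d` (rigid: orthonormal linear block, det = +1).
#' @export
sample_affine <- function(max_translation_um, max_rotation_rad, seed = 1L,
                          center = c(0, 0, 0)) {
  if (any(max_translation_um < 0) || max_rotation_rad < 0)
    stop("sample_affine: bounds must be >= 0")
  with_seed(seed, {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    angle <- runif(1, 0, max_rotation_rad)
    R <- rotation_axis_angle(u, angle)
    if (length(max_translation_um) == 3) {
      t <- runif(3, -1, 1) * max_translation_um
    } else {
      td <- rnorm(3); td <- td / sqrt(sum(td^2))
      t <- td * runif(1, 0, max_translation_um)
    }
    m <- diag(4)
    m[1:3, 1:3] <- R
    m[1:3, 4] <- center + t - R %*% center
    affine3d(m)
  })
}

#' Sample a smooth random displacement field
#'
#' Draws per-component white noise on a coarse control grid with cell size
#' `smoothness_scale_um`, interpolates it trilinearly onto `grid` (so the
#' field carries no structure finer than the control-cell scale) and rescales
#' so the maximum physical displacement magnitude equals `amplitude_um`.
#' Serves as a longitudinal-growth stand-in: smooth non-rigid motion of the
#' vascular bed.
#'
#' @param grid target [grid3d].
#' @param amplitude_um maximum displacement magnitude (um, >= 0).
#' @param smoothness_scale_um control-cell size (um).
#' @param seed integer seed.
#' @return A `ddf`: dense displacement field in voxel units of `grid`.
#' @export
sample_smooth_deformation <- function(grid, amplitude_um, smoothness_scale_um = 400,
                                      seed = 1L) {
  if (amplitude_um < 0) stop("sample_smooth_deformation: amplitude must be >= 0")
  ext <- grid_extent(grid)
  nctrl <- pmax(2L, as.integer(ceiling(ext / smoothness_scale_um)) + 1L)
  cgrid <- grid3d(nctrl, rep(smoothness_scale_um, 3),
                  grid$origin + ext / 2 - (nctrl - 1L) * smoothness_scale_um / 2)
  u_phys <- with_seed(seed, array(rnorm(prod(nctrl) * 3), c(nctrl, 3)))
  comp <- vector("list", 3)
  for (c in 1:3) {
    cv <- .resample_affine_cpp(array(u_phys[, , , c], nctrl), cgrid$shape, cgrid$origin,
                               cgrid$spacing, grid$shape, grid$origin, grid$spacing,
                               diag(4), TRUE)
    comp[[c]] <- array(cv, grid$shape)
  }
  mag <- sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2)
  mmax <- max(mag)
  scale <- if (mmax > 0 && amplitude_um > 0) amplitude_um / mmax else 0
  vec <- array(0, c(grid$shape, 3))
  for (c in 1:3) vec[, , , c] <- comp[[c]] * scale / grid$spacing[c]
  ddf(vec, grid)
}

# Displace tree geometry: affine or forward physical sampling of a ddf.
transform_tree <- function(tree, transform) {
  segs <- tree$segments
  p0 <- as.matrix(segs[, c("x0", "y0", "z0")])
  p1 <- as.matrix(segs[, c("x1", "y1", "z1")])
  if (inherits(transform, "affine3d")) {
    p0 <- apply_affine(transform, p0)
    p1 <- apply_affine(transform, p1)
  } else if (inherits(transform, "ddf")) {
    p0 <- p0 + ddf_displacement_at(transform, p0)
    p1 <- p1 + ddf_displacement_at(transform, p1)
  } else stop("transform_tree: unsupported transform")
  segs[, c("x0", "y0", "z0")] <- p0
  segs[, c("x1", "y1", "z1")] <- p1
  tree$segments <- segs
  tree
}

#' Build a fixed/moving phantom scan pair with known ground truth
#'
#' The fixed scan is the rasterised tree passed through the imaging model.
#' The moving scan re-images the same anatomy after (i) biological
#' variability — a fraction of terminal segments dropped (perfusion loss at
#' the capillary end) and optionally new terminal segments appearing — and
#' (ii) a known geometric ground-truth transform (rigid `affine3d` or smooth
#' `ddf`) applied to the tree, plus fresh imaging noise and a logged
#' scan-to-scan gain factor. Landmarks are branch points that remain
#' bifurcations in both trees; their moving positions are the ground-truth
#' transform applied exactly, so pre-noise landmark TRE under the recorded
#' transform is identically zero.
#'
#' @param tree a `vessel_tree` (the fixed anatomy).
#' @param grid acquisition [grid3d] for both scans.
#' @param transform_spec ground-truth transform: an `affine3d`, a `ddf`, or
#'   NULL for identity.
#' @param variability list with `dropout_fraction` in \[0,1) and
#'   `extra_vessel_count` (new terminal segments in the moving scan).
#' @param imaging_params passed to [apply_imaging_model]; the moving scan's
#'   gain is additionally multiplied by a logged factor drawn in \[0.8, 1.2\].
#' @param seed integer seed driving all randomness.
#' @return An object of class `phantom_pair`.
#' @export
make_pair <- function(tree, grid, transform_spec = NULL,
                      variability = list(dropout_fraction = 0, extra_vessel_count = 0),
                      imaging_params = list(depth_decay_per_mm = 0.5, gain = 1,
                                            gaussian_noise_sd = 0.1,
                                            background_level = 0.05),
                      seed = 1L) {
  dropout <- variability$dropout_fraction %||% 0
  extra <- variability$extra_vessel_count %||% 0
  if (dropout < 0 || dropout >= 1) stop("make_pair: dropout_fraction must be in [0,1)")
  if (is.null(transform_spec)) transform_spec <- affine_identity()

  fixed_ras <- rasterize_tree(tree, grid)
  bp_fixed <- tree_branch_points(tree)

  for (attempt in 1:10) {
    sub <- derive_seed(seed, attempt)
    moving_tree <- with_seed(sub, {
      mt <- tree
      terms <- tree_terminals(mt)
      keep_n <- round((1 - dropout) * length(terms))
      drop_n <- length(terms) - keep_n
      # Drop terminal segments only, and only where the parent keeps another
      # child, so no interior segment silently becomes a new terminal and
      # deeper branch points survive.
      dropped <- 0L
      while (dropped < drop_n) {
        ids <- mt$segments$id
        nch <- as.integer(table(factor(mt$segments$parent, levels = ids)))
        terminal_now <- ids[nch == 0L]
        par <- mt$segments$parent[match(terminal_now, ids)]
        par_nch <- ifelse(par == 0L, 2L, nch[match(par, ids)])
        eligible <- terminal_now[par_nch >= 2L]
        if (length(eligible) == 0) break
        pick <- eligible[sample.int(length(eligible), 1)]
        mt$segments <- mt$segments[mt$segments$id != pick, ]
        dropped <- dropped + 1L
      }
      if (extra > 0) {
        base_id <- max(tree$segments$id)
        for (e in seq_len(extra)) {
          ids <- mt$segments$id
          nch <- as.integer(table(factor(mt$segments$parent, levels = ids)))
          interior <- mt$segments[nch > 0L, ]
          if (nrow(interior) == 0) interior <- mt$segments
          src <- interior[sample.int(nrow(interior), 1), ]
          th <- runif(1, 0, 2 * pi)
          len <- 0.1 * min(grid_extent(grid)[1:2]) * runif(1, 0.6, 1)
          p1 <- c(src$x1 + len * cos(th), src$y1 + len * sin(th),
                  src$z1 + len * 0.1 * runif(1, -1, 1))
          p1 <- pmin(pmax(p1, grid$origin), grid$origin + grid_extent(grid))
          mt$segments <- rbind(mt$segments,
                               data.frame(id = base_id + e, parent = src$id,
                                          gen = src$gen + 1L,
                                          x0 = src$x1, y0 = src$y1, z0 = src$z1,
                                          x1 = p1[1], y1 = p1[2], z1 = p1[3],
                                          radius = max(10, src$radius * 0.6)))
        }
      }
      mt
    })
    # landmarks: branch points still bifurcating in the (pre-transform) moving tree
    bp_moving_pre <- tree_branch_points(moving_tree)
    shared <- intersect(rownames(bp_fixed), rownames(bp_moving_pre))
    if (length(shared) >= 3) break
  }
  if (length(shared) < 3)
    stop("make_pair: fewer than 3 shared branch points after 10 attempts")

  moving_tree_t <- transform_tree(moving_tree, transform_spec)
  moving_ras <- rasterize_tree(moving_tree_t, grid)

  lf <- bp_fixed[shared, , drop = FALSE]
  lg <- if (inherits(transform_spec, "affine3d")) apply_affine(transform_spec, lf)
        else lf + ddf_displacement_at(transform_spec, lf)
  dimnames(lg) <- dimnames(lf)

  gain_factor <- with_seed(derive_seed(seed, 101L), runif(1, 0.8, 1.2))
  ip_moving <- imaging_params
  ip_moving$gain <- (imaging_params$gain %||% 1) * gain_factor
  fixed_v <- apply_imaging_model(fixed_ras$volume, imaging_params,
                                 seed = derive_seed(seed, 201L))
  moving_v <- apply_imaging_model(moving_ras$volume, ip_moving,
                                  seed = derive_seed(seed, 202L))

  structure(list(
    fixed = list(volume = fixed_v, mask = fixed_ras$mask),
    moving = list(volume = moving_v, mask = moving_ras$mask),
    gt_transform = transform_spec,
    landmarks_fixed = lf, landmarks_moving = lg,
    fixed_tree = tree, moving_tree = moving_tree_t,
    log = list(seed = seed, dropout_fraction = dropout, extra_vessel_count = extra,
               gain = imaging_params$gain %||% 1, gain_factor = gain_factor,
               noise_sd = imaging_params$gaussian_noise_sd %||% 0.1,
               transform_type = class(transform_spec)[1])
  ), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %d landmarks, gt = %s, dropout = %g, gain factor = %.3f\n",
              nrow(x$landmarks_fixed), x$log$transform_type,
              x$log$dropout_fraction, x$log$gain_factor))
  print(x$fixed$volume$grid)
  invisible(x)
}
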