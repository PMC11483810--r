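#' Benchmark run configuration
#'
#' Describes a full phantom benchmark: how many scan pairs to simulate, on
#' what grid, which ground-truth motion each pair carries (rigid
#' repositioning between repeated scans, or a smooth deformation emulating
#' longitudinal change), which registration methods to run, and how the
#' deformable model is trained. Grid dimensions must be divisible by 16 when
#' the deformable method is included.
#'
#' @param n_pairs number of simulated pairs.
#' @param grid acquisition [grid3d].
#' @param methods subset of `c("mi", "ncc", "distance", "icp", "localnet")`.
#' @param transform_types per-pair ground-truth type, recycled to
#'   `n_pairs`: `"rigid"` or `"smooth"`.
#' @param rigid_bounds list with `max_translation_um`, `max_rotation_rad`.
#' @param smooth_amplitude_um,smooth_scale_um smooth-deformation parameters.
#' @param tree_params branching parameters for [generate_vessel_tree].
#' @param variability dropout/appearance settings for [make_pair].
#' @param imaging imaging-model parameters for [make_pair].
#' @param preprocess a [preprocess_config] applied to intensity volumes
#'   before intensity-based registration and intensity metrics.
#' @param opts [optimizer_settings] for the affine methods.
#' @param train [train_config] for the deformable method.
#' @param seed master seed; every pair and stage derives its own sub-seed.
#' @param out_dir optional output directory for CSV reports, overlays and
#'   the provenance record.
#' @export
benchmark_config <- function(n_pairs = 12L,
                             grid = grid3d(c(64, 64, 32), c(20, 20, 4)),
                             methods = c("mi", "ncc", "distance", "icp", "localnet"),
                             transform_types = c("rigid", "smooth"),
                             rigid_bounds = list(max_translation_um = c(150, 150, 20),
                                                 max_rotation_rad = 5 * pi / 180),
                             smooth_amplitude_um = 60,
                             smooth_scale_um = 500,
                             tree_params = list(depth = 5, branch_prob = 0.8,
                                                radius_range = c(15, 28),
                                                tortuosity = 0.2),
                             variability = list(dropout_fraction = 0.1,
                                                extra_vessel_count = 1),
                             imaging = list(depth_decay_per_mm = 0.5, gain = 1,
                                            gaussian_noise_sd = 0.08,
                                            background_level = 0.05),
                             preprocess = preprocess_config(stages = c("wiener", "clip_zscore")),
                             opts = optimizer_settings(),
                             train = train_config(epochs = 25L),
                             seed = 1L, out_dir = NULL) {
  structure(list(n_pairs = as.integer(n_pairs), grid = grid, methods = methods,
                 transform_types = rep(transform_types, length.out = n_pairs),
                 rigid_bounds = rigid_bounds,
                 smooth_amplitude_um = smooth_amplitude_um,
                 smooth_scale_um = smooth_scale_um,
                 tree_params = tree_params, variability = variability,
                 imaging = imaging, preprocess = preprocess, opts = opts,
                 train = train, seed = as.integer(seed), out_dir = out_dir),
            class = "benchmark_config")
}

#' Simulate the benchmark's phantom pair set
#'
#' @param cfg a [benchmark_config].
#' @return list of `phantom_pair`s (attribute `transform_type` per pair).
#' @export
simulate_pairs <- function(cfg) {
  lapply(seq_len(cfg$n_pairs), function(p) {
    tree <- generate_vessel_tree(cfg$grid, cfg$tree_params,
                                 seed = derive_seed(cfg$seed, p))
    ttype <- cfg$transform_types[p]
    gt <- if (ttype == "rigid") {
      sample_affine(cfg$rigid_bounds$max_translation_um,
                    cfg$rigid_bounds$max_rotation_rad,
                    seed = derive_seed(cfg$seed, 1000L + p),
                    center = grid_centre(cfg$grid))
    } else {
      sample_smooth_deformation(cfg$grid, cfg$smooth_amplitude_um,
                                cfg$smooth_scale_um,
                                seed = derive_seed(cfg$seed, 2000L + p))
    }
    pair <- make_pair(tree, cfg$grid, gt, cfg$variability, cfg$imaging,
                      seed = derive_seed(cfg$seed, 3000L + p))
    attr(pair, "transform_type") <- ttype
    pair
  })
}

# Initialisation policy: repeated-scan (rigid) pairs start from centres of
# mass; longitudinal-analogue (smooth-deformation) pairs start from rigid
# landmark alignment, mirroring how manually selected branch points are
# used when the anatomy has changed between scans.
pair_init <- function(pair, ptype) {
  if (identical(ptype, "smooth"))
    landmark_initialize(pair$landmarks_fixed, pair$landmarks_moving)
  else NULL  # register_affine defaults to centre-of-mass
}

# Register one pair with one affine-family method; returns transform +
# warped volume/mask on the fixed grid.
run_affine_method <- function(method, fpp, gpp, pair, opts, init = NULL) {
  res <- switch(method,
    mi = register_affine(fpp, gpp, similarity_metric("mi"), init = init, opts = opts),
    ncc = register_affine(fpp, gpp, similarity_metric("ncc"), init = init, opts = opts),
    distance = register_distance(pair$fixed$mask, pair$moving$mask, opts = opts),
    icp = icp_point_to_plane(extract_surface(pair$fixed$mask),
                             extract_surface(pair$moving$mask)),
    stop("unknown method: ", method))
  t <- res$transform
  list(result = res, transform = t,
       warped_volume = warp(gpp, t, grid = fpp$grid),
       warped_mask = warp(pair$moving$mask, t, grid = pair$fixed$mask$grid))
}

#' Run the full co-registration benchmark
#'
#' For every simulated pair and every selected method: pre-process,
#' register, warp, and score with the quality-metric panel; then compare
#' methods pairwise on the percent changes (Wilcoxon + Holm). The first
#' scan of each pair is always the fixed image. A failing stage is logged
#' and the run continues with the remaining pairs. With `out_dir` set,
#' per-pair reports, the comparison table, MIP overlays of the first pair
#' and a provenance record (config, seeds, package version) are written;
#' reruns with an identical config produce identical files.
#'
#' @param cfg a [benchmark_config].
#' @param pairs optionally, a pre-simulated pair list (default: simulate
#'   from `cfg`).
#' @return list with `reports` (tibble of per-pair metric rows),
#'   `comparisons` (tibble from [compare_methods]), `pair_types`,
#'   `failures`, and `model` (the trained deformable model, if run).
#' @export
run_benchmark <- function(cfg = benchmark_config(), pairs = NULL) {
  if (is.null(pairs)) pairs <- simulate_pairs(cfg)
  n <- length(pairs)
  pair_ids <- sprintf("pair%02d", seq_len(n))
  pair_types <- vapply(pairs, function(p) attr(p, "transform_type") %||% "rigid",
                       character(1))

  pp <- lapply(pairs, function(pair) {
    list(f = preprocess_volume(pair$fixed$volume, cfg$preprocess),
         g = preprocess_volume(pair$moving$volume, cfg$preprocess))
  })

  model <- NULL
  if ("localnet" %in% cfg$methods) {
    if (any(cfg$grid$shape %% 16L != 0L))
      stop("run_benchmark: grid dims must be divisible by 16 for the deformable method")
    model <- train_deformable(pairs, cfg$train,
                              pre_align = ifelse(pair_types == "smooth",
                                                 "landmarks", "com"))$model
  }

  reports <- list()
  failures <- list()
  for (i in seq_len(n)) {
    pair <- pairs[[i]]
    for (method in cfg$methods) {
      res <- tryCatch({
        if (method == "localnet") {
          # pre-registration state is the original moving scan, as for every
          # other method; the deformable warp includes the rigid pre-alignment
          r <- register_deformable(pair, model,
                                   pre_align = if (pair_types[i] == "smooth")
                                     "landmarks" else "com")
          evaluate_pair(list(volume = pp[[i]]$f, mask = pair$fixed$mask),
                        list(volume = pp[[i]]$g, mask = pair$moving$mask),
                        list(volume = preprocess_volume(r$warped, cfg$preprocess),
                             mask = r$warped_mask),
                        transform = r$transform,
                        landmarks_fixed = pair$landmarks_fixed,
                        landmarks_moving = pair$landmarks_moving,
                        method = method, pair_id = pair_ids[i])
        } else {
          r <- run_affine_method(method, pp[[i]]$f, pp[[i]]$g, pair, cfg$opts,
                                 init = if (method %in% c("mi", "ncc"))
                                   pair_init(pair, pair_types[i]) else NULL)
          evaluate_pair(list(volume = pp[[i]]$f, mask = pair$fixed$mask),
                        list(volume = pp[[i]]$g, mask = pair$moving$mask),
                        list(volume = r$warped_volume, mask = r$warped_mask),
                        transform = r$transform,
                        landmarks_fixed = pair$landmarks_fixed,
                        landmarks_moving = pair$landmarks_moving,
                        method = method, pair_id = pair_ids[i])
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- list(pair = pair_ids[i], method = method,
                                                 message = conditionMessage(res))
      } else reports[[length(reports) + 1]] <- res
    }
  }
  reports <- do.call(rbind, reports)
  comparisons <- if (length(unique(reports$method)) >= 2)
    compare_methods(reports) else NULL

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(reports, file.path(cfg$out_dir, "reports.csv"), row.names = FALSE)
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"),
                row.names = FALSE)
    ov <- render_mip_overlay(pp[[1]]$f, pp[[1]]$g)
    save_overlay_png(ov, file.path(cfg$out_dir, "pair01_pre_overlay.png"))
    prov <- list(package_version = as.character(utils::packageVersion("mesoreg")),
                 seed = cfg$seed, n_pairs = cfg$n_pairs,
                 grid = list(shape = cfg$grid$shape, spacing = cfg$grid$spacing),
                 methods = cfg$methods, transform_types = pair_types,
                 rigid_bounds = cfg$rigid_bounds,
                 smooth_amplitude_um = cfg$smooth_amplitude_um,
                 variability = cfg$variability, imaging = cfg$imaging,
                 failures = failures)
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(reports = reports, comparisons = comparisons, pair_types = pair_types,
       failures = failures, model = model)
}
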