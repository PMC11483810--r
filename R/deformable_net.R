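#' Training configuration for deformable registration
#'
#' The network is a 4-level 3D encoder-decoder with skip connections taking
#' the stacked fixed/moving intensity + segmentation channels (4 input
#' channels, fixed order: fixed intensity, fixed segmentation, moving
#' intensity, moving segmentation) and predicting a 3-channel dense
#' displacement field in voxel units of the fixed grid. Desk-scale defaults
#' (small channel counts, 64^3-class crops, tens to a couple hundred epochs)
#' keep single-CPU training tractable; crop dimensions must be divisible by
#' 2^4 = 16.
#'
#' @param channels feature channels of the four encoder levels.
#' @param learning_rate Adam learning rate. The desk-scale default (1e-3)
#'   compensates for running ~50x fewer optimisation steps than a
#'   full-scale 1000-epoch training schedule, where 1e-4 is the
#'   appropriate setting.
#' @param epochs training epochs.
#' @param batch batch size (only 1 is supported; volumes are large).
#' @param augment_max_rot maximum magnitude of random z-rotations (rad)
#'   applied jointly to both scans of a pair for augmentation.
#' @param augment logical; enable the rotation augmentation.
#' @param seed integer seed controlling initialisation, shuffling and
#'   augmentation.
#' @export
train_config <- function(channels = c(4, 8, 16, 32), learning_rate = 1e-3,
                         epochs = 100L, batch = 1L,
                         augment_max_rot = pi / 15, augment = FALSE,
                         seed = 1L) {
  stopifnot(length(channels) == 4, learning_rate > 0, batch == 1L)
  structure(list(depth = 4L, channels = as.integer(channels),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch = 1L, augment_max_rot = augment_max_rot,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

he_init <- function(nrow, ncol, fan_in, gain = 1) {
  matrix(rnorm(nrow * ncol, 0, gain * sqrt(2 / fan_in)), nrow, ncol)
}

#' Build the deformable-registration network
#'
#' Initialises all convolution weights with He initialisation; the final
#' 1x1x1 head is He-initialised and then scaled down (x0.01) so the initial
#' displacement field is near zero and training starts from an
#' (almost-)identity warp.
#'
#' @param cfg a [train_config].
#' @return A `localnet_model`: parameter list plus configuration.
#' @export
build_network <- function(cfg = train_config()) {
  ch <- cfg$channels
  cin <- 4L
  with_seed(cfg$seed, {
    p <- list()
    ins <- c(cin, ch[1], ch[2], ch[3])
    for (k in 1:4) {
      p[[paste0("enc", k, ".W")]] <- he_init(27 * ins[k], ch[k], 27 * ins[k])
      p[[paste0("enc", k, ".b")]] <- rep(0, ch[k])
    }
    p[["bn.W"]] <- he_init(27 * ch[4], ch[4], 27 * ch[4])
    p[["bn.b"]] <- rep(0, ch[4])
    douts <- c(ch[3], ch[2], ch[1], ch[1])   # dec4 (deepest), dec3, dec2, dec1
    # decoder input channels: upsampled previous output + same-scale skip
    dins <- c(ch[4] + ch[4], douts[1] + ch[3], douts[2] + ch[2], douts[3] + ch[1])
    for (k in 1:4) {
      nm <- paste0("dec", 5L - k)            # dec4 is the deepest level
      p[[paste0(nm, ".W")]] <- he_init(27 * dins[k], douts[k], 27 * dins[k])
      p[[paste0(nm, ".b")]] <- rep(0, douts[k])
    }
    p[["head.W"]] <- he_init(douts[4], 3, douts[4], gain = 0.01)
    p[["head.b"]] <- rep(0, 3)
    structure(list(params = p, cfg = cfg, channels = ch,
                   dec_in = dins, dec_out = douts),
              class = "localnet_model")
  })
}

#' @export
print.localnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<localnet_model> 4-level encoder-decoder, channels (%s), %d parameters\n",
              paste(x$channels, collapse = ", "), np))
  invisible(x)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }

nchan <- function(x) dim(x)[4]
dim3 <- function(x) dim(x)[1:3]

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Forward pass; returns ddf array and a cache for backprop.
localnet_forward <- function(model, x) {
  p <- model$params
  cache <- list(x = x)
  conv_relu <- function(inp, name) {
    pre <- .conv3d_fwd_cpp(inp, dim3(inp), nchan(inp), p[[paste0(name, ".W")]],
                           p[[paste0(name, ".b")]])
    act <- relu_fwd(pre)
    cache[[paste0(name, ".in")]] <<- inp
    cache[[paste0(name, ".act")]] <<- act
    act
  }
  e1 <- conv_relu(x, "enc1")
  p1 <- .avgpool2_fwd_cpp(e1, dim3(e1), nchan(e1))
  e2 <- conv_relu(p1, "enc2")
  p2 <- .avgpool2_fwd_cpp(e2, dim3(e2), nchan(e2))
  e3 <- conv_relu(p2, "enc3")
  p3 <- .avgpool2_fwd_cpp(e3, dim3(e3), nchan(e3))
  e4 <- conv_relu(p3, "enc4")
  p4 <- .avgpool2_fwd_cpp(e4, dim3(e4), nchan(e4))
  bn <- conv_relu(p4, "bn")
  u4 <- .upsample2_fwd_cpp(bn, dim3(bn), nchan(bn))
  d4 <- conv_relu(concat_ch(u4, e4), "dec4")
  u3 <- .upsample2_fwd_cpp(d4, dim3(d4), nchan(d4))
  d3 <- conv_relu(concat_ch(u3, e3), "dec3")
  u2 <- .upsample2_fwd_cpp(d3, dim3(d3), nchan(d3))
  d2 <- conv_relu(concat_ch(u2, e2), "dec2")
  u1 <- .upsample2_fwd_cpp(d2, dim3(d2), nchan(d2))
  d1 <- conv_relu(concat_ch(u1, e1), "dec1")
  # 1x1x1 head: plain matrix product over channels
  dd <- dim(d1)
  flat <- matrix(d1, ncol = dd[4])
  ddf_flat <- flat %*% p[["head.W"]]
  ddf_flat <- sweep(ddf_flat, 2, p[["head.b"]], `+`)
  cache$head.in <- d1
  list(ddf = array(ddf_flat, c(dd[1:3], 3)), cache = cache)
}

# Backward pass from gradient w.r.t. the ddf; returns parameter gradients.
localnet_backward <- function(model, cache, g_ddf) {
  p <- model$params
  grads <- list()
  dd <- dim(cache$head.in)
  gflat <- matrix(g_ddf, ncol = 3)
  hin <- matrix(cache$head.in, ncol = dd[4])
  grads[["head.W"]] <- crossprod(hin, gflat)
  grads[["head.b"]] <- colSums(gflat)
  g <- array(gflat %*% t(p[["head.W"]]), dd)

  conv_bwd <- function(g, name) {
    act <- cache[[paste0(name, ".act")]]
    g[act <= 0] <- 0
    inp <- cache[[paste0(name, ".in")]]
    r <- .conv3d_bwd_cpp(inp, dim3(inp), nchan(inp), p[[paste0(name, ".W")]], g)
    grads[[paste0(name, ".W")]] <<- r$gw
    grads[[paste0(name, ".b")]] <<- r$gb
    r$gx
  }
  split_ch <- function(g, n1) {
    list(a = g[, , , seq_len(n1), drop = FALSE],
         b = g[, , , -seq_len(n1), drop = FALSE])
  }
  ch <- model$channels

  g <- conv_bwd(g, "dec1")
  s <- split_ch(g, model$dec_out[3])  # up(d2) channels, then skip e1
  g_e1_skip <- s$b
  g <- .upsample2_bwd_cpp(s$a, dim(s$a)[1:3], dim(s$a)[4])
  g <- conv_bwd(g, "dec2")
  s <- split_ch(g, model$dec_out[2])
  g_e2_skip <- s$b
  g <- .upsample2_bwd_cpp(s$a, dim(s$a)[1:3], dim(s$a)[4])
  g <- conv_bwd(g, "dec3")
  s <- split_ch(g, model$dec_out[1])
  g_e3_skip <- s$b
  g <- .upsample2_bwd_cpp(s$a, dim(s$a)[1:3], dim(s$a)[4])
  g <- conv_bwd(g, "dec4")
  s <- split_ch(g, ch[4])
  g_e4_skip <- s$b
  g <- .upsample2_bwd_cpp(s$a, dim(s$a)[1:3], dim(s$a)[4])
  g <- conv_bwd(g, "bn")
  g <- .avgpool2_bwd_cpp(g, dim(cache[["enc4.act"]])[1:3], ch[4]) + g_e4_skip
  g <- conv_bwd(g, "enc4")
  g <- .avgpool2_bwd_cpp(g, dim(cache[["enc3.act"]])[1:3], ch[3]) + g_e3_skip
  g <- conv_bwd(g, "enc3")
  g <- .avgpool2_bwd_cpp(g, dim(cache[["enc2.act"]])[1:3], ch[2]) + g_e2_skip
  g <- conv_bwd(g, "enc2")
  g <- .avgpool2_bwd_cpp(g, dim(cache[["enc1.act"]])[1:3], ch[1]) + g_e1_skip
  g <- conv_bwd(g, "enc1")
  grads
}

# Min-max normalise a volume's intensities to [0, 1].
normalise01 <- function(vals) {
  r <- range(vals)
  if (r[2] <= r[1]) return(array(0, dim(vals)))
  (vals - r[1]) / (r[2] - r[1])
}

# Centre-crop a grid's dims down to multiples of 16; returns index ranges.
crop16_ranges <- function(shape) {
  tgt <- pmax(16L, (shape %/% 16L) * 16L)
  if (any(tgt > shape)) stop("deformable input dims must be >= 16 per axis")
  lapply(1:3, function(a) {
    off <- (shape[a] - tgt[a]) %/% 2L
    seq.int(off + 1L, off + tgt[a])
  })
}

#' Prepare a phantom pair as network input
#'
#' Applies a rigid pre-alignment (centre-of-mass by default, or landmark
#' alignment) to the moving scan, min-max normalises intensities, and
#' centre-crops to dimensions divisible by 16. The network then only has to
#' learn the residual non-rigid deformation.
#'
#' @param pair a `phantom_pair` (or list with `fixed`/`moving` volume+mask).
#' @param pre_align `"com"`, `"landmarks"` or `"none"`.
#' @return list with the 4-channel input array, the cropped fixed
#'   volume/mask, the cropped grid and the `init` transform.
#' @export
deformable_input <- function(pair, pre_align = c("com", "landmarks", "none")) {
  pre_align <- match.arg(pre_align)
  fv <- pair$fixed$volume; fm <- pair$fixed$mask
  gv <- pair$moving$volume; gm <- pair$moving$mask
  init <- switch(pre_align,
                 com = com_initialize(fv, gv),
                 landmarks = landmark_initialize(pair$landmarks_fixed, pair$landmarks_moving),
                 none = affine_identity())
  gva <- warp(gv, init, grid = fv$grid)
  gma <- warp(gm, init, grid = fv$grid)
  rg <- crop16_ranges(fv$grid$shape)
  cropg <- grid3d(vapply(rg, length, integer(1)), fv$grid$spacing,
                  fv$grid$origin + (vapply(rg, min, numeric(1)) - 1) * fv$grid$spacing)
  cr <- function(a) a[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  x <- array(0, c(cropg$shape, 4))
  x[, , , 1] <- normalise01(cr(fv$values))
  x[, , , 2] <- cr(fm$values)
  x[, , , 3] <- normalise01(cr(gva$values))
  x[, , , 4] <- cr(gma$values)
  list(input = x,
       fixed_volume = volume3d(cr(fv$values), cropg),
       fixed_mask = binary_mask(cr(fm$values), cropg),
       moving_volume = volume3d(cr(gva$values), cropg),
       moving_mask = binary_mask(cr(gma$values), cropg),
       grid = cropg, init = init)
}

# Loss value and ddf gradient for one prepared input and predicted field.
# The input channels already hold the normalised intensities and masks.
deformable_loss_terms <- function(prep, u) {
  dm <- dim(u)[1:3]
  fv <- array(prep$input[, , , 1], dm)
  fm <- array(prep$input[, , , 2], dm)
  gv <- array(prep$input[, , , 3], dm)
  gm <- array(prep$input[, , , 4], dm)
  wv <- array(.ddf_warp_cpp(gv, dm, u, TRUE), dm)
  wm <- array(.ddf_warp_cpp(gm, dm, u, TRUE), dm)
  wm <- pmin(pmax(wm, 0), 1)
  # NCC term
  fc <- fv - mean(fv); wc <- wv - mean(wv)
  nf <- sqrt(sum(fc^2)); nw <- sqrt(sum(wc^2))
  if (nw == 0) { nccv <- 0; g_wv <- array(0, dm) } else {
    nccv <- sum(fc * wc) / (nf * nw)
    raw <- fc / (nf * nw) - nccv * wc / nw^2
    g_wv <- -(raw - mean(raw))  # d(-NCC)/d warped intensity
  }
  gd <- gdl_terms(fm, wm)
  fld <- ddf(u, grid3d(dm, prep$grid$spacing, prep$grid$origin))
  bev <- bending_energy(fld)
  loss <- -nccv + gd$value + bev
  gu <- .ddf_warp_grad_cpp(gv, dm, u, g_wv) +
        .ddf_warp_grad_cpp(gm, dm, u, gd$grad) +
        bending_energy_grad(fld)
  list(loss = loss, grad = array(gu, c(dm, 3)),
       ncc = nccv, gdl = gd$value, be = bev)
}

# Random z-rotation augmentation applied jointly to both scans of a pair.
augment_rotate_z <- function(prep, angle) {
  g <- prep$grid
  t <- affine_rigid(rotation = c(0, 0, angle), center = grid_centre(g))
  rot_v <- function(vol) warp(vol, t, grid = g)
  rot_m <- function(m) warp(m, t, grid = g)
  prep$fixed_volume <- rot_v(prep$fixed_volume)
  prep$fixed_mask <- rot_m(prep$fixed_mask)
  prep$moving_volume <- rot_v(prep$moving_volume)
  prep$moving_mask <- rot_m(prep$moving_mask)
  prep$input[, , , 1] <- normalise01(prep$fixed_volume$values)
  prep$input[, , , 2] <- prep$fixed_mask$values
  prep$input[, , , 3] <- normalise01(prep$moving_volume$values)
  prep$input[, , , 4] <- prep$moving_mask$values
  prep
}

#' Split pairs into training and validation sets
#'
#' @param pairs list of `phantom_pair`s.
#' @param fraction fraction assigned to training (default 0.5).
#' @param seed integer seed.
#' @return list with `train` and `validation` pair lists.
#' @export
split_pairs <- function(pairs, fraction = 0.5, seed = 1L) {
  n <- length(pairs)
  ntr <- max(1L, round(fraction * n))
  idx <- with_seed(seed, sample.int(n))
  list(train = pairs[idx[seq_len(ntr)]],
       validation = pairs[idx[-seq_len(ntr)]])
}

#' Train the deformable registration network
#'
#' Weakly supervised training: the network never sees the ground-truth
#' transform, only the composite loss (negative NCC + generalised Dice +
#' bending energy) of its own warps, minimised with Adam at batch size 1.
#' The model state with the best validation loss (training loss when no
#' validation pairs are supplied) is returned alongside the per-epoch mean
#' loss traces. Fully deterministic for a fixed seed.
#'
#' @param pairs list of `phantom_pair`s for training (>= 1).
#' @param cfg a [train_config].
#' @param validation optional list of `phantom_pair`s.
#' @param pre_align rigid pre-alignment mode(s) passed to
#'   [deformable_input]; a single mode or one per training pair.
#' @return list with `model`, `loss_trace`, `val_trace`, `best_epoch`.
#' @export
train_deformable <- function(pairs, cfg = train_config(), validation = NULL,
                             pre_align = "com") {
  if (length(pairs) == 0) stop("train_deformable: empty pair list")
  model <- build_network(cfg)
  pa <- rep(pre_align, length.out = length(pairs))
  preps <- Map(function(p, a) deformable_input(p, pre_align = a), pairs, pa)
  vpreps <- lapply(validation %||% list(), deformable_input, pre_align = pre_align[1])
  if (cfg$epochs == 0L)
    return(list(model = model, loss_trace = numeric(0), val_trace = numeric(0),
                best_epoch = 0L))

  # Adam state
  mstate <- lapply(model$params, function(w) array(0, dim(w) %||% length(w)))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_trace <- numeric(cfg$epochs)
  val_trace <- numeric(cfg$epochs)
  best <- list(loss = Inf, params = model$params, epoch = 0L)

  val_loss <- function() {
    if (length(vpreps) == 0) return(NA_real_)
    mean(vapply(vpreps, function(pr) {
      u <- localnet_forward(model, pr$input)$ddf
      deformable_loss_terms(pr, u)$loss
    }, numeric(1)))
  }

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(preps))
      ep_losses <- numeric(length(ord))
      for (t in seq_along(ord)) {
        pr <- preps[[ord[t]]]
        if (cfg$augment) {
          ang <- runif(1, -cfg$augment_max_rot, cfg$augment_max_rot)
          pr <- augment_rotate_z(pr, ang)
        }
        fwd <- localnet_forward(model, pr$input)
        lt <- deformable_loss_terms(pr, fwd$ddf)
        ep_losses[t] <- lt$loss
        grads <- localnet_backward(model, fwd$cache, lt$grad)
        step <- step + 1L
        for (nm in names(model$params)) {
          gnm <- grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gnm
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gnm^2
          mhat <- mstate[[nm]] / (1 - b1^step)
          vhat <- vstate[[nm]] / (1 - b2^step)
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_trace[ep] <- mean(ep_losses)
      vl <- val_loss()
      val_trace[ep] <- vl
      sel <- if (is.na(vl)) loss_trace[ep] else vl
      if (sel < best$loss) best <- list(loss = sel, params = model$params, epoch = ep)
    }
  })
  model$params <- best$params
  list(model = model, loss_trace = loss_trace, val_trace = val_trace,
       best_epoch = best$epoch)
}

#' Deformable registration of a pair with a trained model
#'
#' Runs the rigid pre-alignment, predicts the dense displacement field with
#' the trained network, and warps the moving volume and mask onto the fixed
#' grid. The returned transform composes the field with the pre-alignment
#' for landmark propagation.
#'
#' @param pair a `phantom_pair` (or compatible list).
#' @param model a trained `localnet_model`.
#' @param pre_align pre-alignment mode (see [deformable_input]).
#' @return A `registration_result` with a `ddf_transform`, the predicted
#'   `field`, and warped moving volume/mask on the cropped fixed grid.
#' @export
register_deformable <- function(pair, model, pre_align = "com") {
  prep <- deformable_input(pair, pre_align = pre_align)
  u <- localnet_forward(model, prep$input)$ddf
  field <- ddf(u, prep$grid)
  transform <- structure(list(init = prep$init, field = field),
                         class = "ddf_transform")
  structure(list(transform = transform, field = field, init = prep$init,
                 warped = warp_with_ddf(prep$moving_volume, field),
                 warped_mask = warp_with_ddf(prep$moving_mask, field),
                 fixed_volume = prep$fixed_volume, fixed_mask = prep$fixed_mask,
                 moving_volume = prep$moving_volume, moving_mask = prep$moving_mask,
                 metric = "localnet", iterations = 0L, converged = TRUE,
                 metric_trace = numeric(0)),
            class = "registration_result")
}
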