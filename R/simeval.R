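# Self-supervised similarity evaluator. Training pairs are built from a
# single volume M: two random spatial transforms K1, K2 give M1 and M2; M1 is
# then corrupted with dual-structure morphology plus Gaussian noise to create
# an appearance (distribution) gap while the spatial gap is known. A residual
# 3D convolutional regressor learns to predict the spatial-error magnitude
# mean |M2 - M1| from the corrupted pair, and the frozen regressor then
# serves as a differentiable multimodal similarity for registration.

#' Random spatial transform specification
#'
#' Rotation is drawn per axis in degrees, translation per axis in voxels,
#' scaling isotropically; optionally a smooth random per-voxel displacement
#' is added. Ranges default to small perturbations (rotation and translation
#' within +/- 3, scale within +/- 8%).
#'
#' @param seed optional seed; two draws with the same seed are identical.
#' @param rot_range degrees, default `c(-3, 3)`.
#' @param trans_range voxels, default `c(-3, 3)`.
#' @param scale_range isotropic scale factor, default `c(0.92, 1.08)`.
#' @param warp_amp amplitude (voxels) of the smooth random per-voxel field
#'   (0 disables it).
#' @param warp_sigma smoothness (voxels) of the random field.
#' @return Object of class `wm_transform`.
#' @export
sample_transform <- function(seed = NULL, rot_range = c(-3, 3),
                             trans_range = c(-3, 3), scale_range = c(0.92, 1.08),
                             warp_amp = 1, warp_sigma = 4) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(rot = runif(3, rot_range[1], rot_range[2]),
                 trans = runif(3, trans_range[1], trans_range[2]),
                 scale = runif(1, scale_range[1], scale_range[2]),
                 warp_amp = warp_amp, warp_sigma = warp_sigma,
                 warp_seed = if (warp_amp > 0) sample.int(2^30, 1) else NA_integer_),
            class = "wm_transform")
}

#' Identity transform
#' @return A `wm_transform` leaving volumes unchanged.
#' @export
identity_transform <- function() {
  structure(list(rot = c(0, 0, 0), trans = c(0, 0, 0), scale = 1,
                 warp_amp = 0, warp_sigma = 4, warp_seed = NA_integer_),
            class = "wm_transform")
}

rotmat3 <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# Smooth zero-mean random displacement (Gaussian random field), RMS-magnitude
# `amp` voxels.
random_smooth_field <- function(shape, amp, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- array(0, dim = c(shape, 3L))
  for (a in 1:3) {
    r <- smooth_gauss(array(rnorm(prod(shape)), dim = shape), sigma)
    r <- r - mean(r)
    s <- sd(as.vector(r))
    if (s > 0) r <- r / s
    u[, , , a] <- r * amp / sqrt(3)
  }
  u
}

#' Apply a spatial transform to a volume
#'
#' Samples `vol` at `R * s * (x - c) + c + t` (rotation/scale about the
#' volume centre, then translation in the warp convention `out(x) =
#' in(x + u)`), followed by the optional smooth random per-voxel field;
#' trilinear interpolation with border clamping.
#'
#' @param vol a [wm_volume] or 3D array.
#' @param spec a `wm_transform`.
#' @return Same kind as `vol`.
#' @export
apply_transform <- function(vol, spec) {
  stopifnot(inherits(spec, "wm_transform"))
  arr <- if (inherits(vol, "wm_volume")) vol$data else vol
  d <- dim(arr)
  ctr <- (d - 1) / 2
  g <- identity_grid(d)
  A <- rotmat3(spec$rot) * spec$scale
  co <- sweep(g, 2L, ctr) %*% t(A)
  co <- sweep(co, 2L, ctr + spec$trans, `+`)
  if (spec$warp_amp > 0) {
    u <- random_smooth_field(d, spec$warp_amp, spec$warp_sigma, spec$warp_seed)
    co <- co + matrix(u, ncol = 3L)
  }
  v <- cpp_sample3(as.double(arr), as.integer(c(d, 1L)), co, FALSE)
  dim(v) <- d
  if (inherits(vol, "wm_volume")) wm_volume(v, vol$spacing, vol$origin, vol$modality) else v
}

#' Build one evaluator training sample
#'
#' Applies two random transforms K1, K2 to the source volume, corrupts the
#' K1 copy with a randomly chosen dual-structure morphology operator (radius
#' drawn from the configured set, ring width 2) plus Gaussian noise, and
#' labels the pair with the true spatial-error magnitude `mean |M2 - M1|`
#' computed from the *uncorrupted* images.
#'
#' @param M source [wm_volume] or 3D array with intensities in \[0, 1\].
#' @param radii candidate outer radii for the morphology corruption.
#' @param noise_sd Gaussian noise sd (intensity units; default 0.05 of the
#'   unit range).
#' @param seed reproducibility seed for the transforms, corruption and noise.
#' @param warp_amp random per-voxel deformation amplitude inside K1/K2.
#' @return Object of class `wm_evalsample`: `input` (H x W x L x 2 array:
#'   channel 1 = M2, channel 2 = corrupted M1), `target` (scalar >= 0), and
#'   `meta`.
#' @export
make_sample <- function(M, radii = c(3, 5, 6, 7, 9), noise_sd = 0.05, seed = NULL,
                        warp_amp = 1) {
  arr <- if (inherits(M, "wm_volume")) M$data else M
  if (!is.null(seed)) set.seed(seed)
  # per-sample magnitude factor so spatial-error targets span from ~0 up to
  # the full transform range (anchors the regression at both ends)
  u <- runif(1)
  k1 <- sample_transform(rot_range = u * c(-3, 3), trans_range = u * c(-3, 3),
                         scale_range = 1 + u * c(-0.08, 0.08), warp_amp = u * warp_amp)
  k2 <- sample_transform(rot_range = u * c(-3, 3), trans_range = u * c(-3, 3),
                         scale_range = 1 + u * c(-0.08, 0.08), warp_amp = u * warp_amp)
  r <- sample(radii, 1)
  op <- sample(c("dual_open", "dual_close"), 1)
  m1 <- apply_transform(arr, k1)
  m2 <- apply_transform(arr, k2)
  pair <- structuring_pair(r, max(1, r - 2))
  corrupted <- if (op == "dual_open") dual_open(m1, pair) else dual_close(m1, pair)
  corrupted <- corrupted + array(rnorm(length(m1), sd = noise_sd), dim = dim(m1))
  structure(list(input = array(c(m2, corrupted), dim = c(dim(arr), 2L)),
                 target = mean(abs(m2 - m1)),
                 meta = list(k1 = k1, k2 = k2, radius = r, op = op,
                             noise_sd = noise_sd, seed = seed)),
            class = "wm_evalsample")
}

# ---- evaluator network -----------------------------------------------------

#' Evaluator network configuration
#'
#' A compact residual 3D convolutional regressor: strided stem, two residual
#' blocks with a channel-doubling downsample between them, global average
#' pooling and a linear head with softplus output (predictions are
#' non-negative). Inputs are average-pooled by `pool_in` before the stem so
#' the evaluator is cheap and scale-tolerant; it is fully convolutional and
#' accepts any input shape.
#'
#' @param channels stem width (doubled after the downsample).
#' @param pool_in integer input pooling factor (1 disables).
#' @return Object of class `wm_evalconfig`.
#' @export
evaluator_config <- function(channels = 8L, pool_in = 2L) {
  structure(list(channels = as.integer(channels), pool_in = as.integer(pool_in)),
            class = "wm_evalconfig")
}

evaluator_params <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ps <- param_set()
  C <- cfg$channels
  ps_conv(ps, "ev.stem", 3L, 2L, C)
  ps_conv(ps, "ev.r1a", 3L, C, C)
  ps_conv(ps, "ev.r1b", 3L, C, C)
  ps_conv(ps, "ev.down", 3L, C, 2L * C)
  ps_conv(ps, "ev.r2a", 3L, 2L * C, 2L * C)
  ps_conv(ps, "ev.r2b", 3L, 2L * C, 2L * C)
  ps_linear(ps, "ev.head", 2L * C, 1L, sd = 0.1)
  class(ps) <- c("wm_params", class(ps))
  ps
}

# Forward pass on a tape; x node is [H,W,L,2]. When trainable = FALSE the
# parameters enter as constants (frozen evaluator used as a loss).
evaluator_tape <- function(tape, ps, cfg, x, trainable = TRUE) {
  wt <- if (trainable) function(n) ad_weight(tape, ps, n)
        else function(n) ad_input(tape, ps[[n]])
  d <- dim(x$v)[1:3]
  if (cfg$pool_in > 1L && all(d >= 2L * cfg$pool_in)) {
    # anti-aliased average pooling (depthwise box conv, stride = factor)
    f <- cfg$pool_in
    nc <- dim(x$v)[4]
    ker <- array(0, dim = c(f, f, f, nc, nc))
    for (c in seq_len(nc)) ker[, , , c, c] <- 1 / f^3
    x <- op_conv3(tape, x, ad_input(tape, ker), ad_input(tape, numeric(nc)),
                  stride = f, pad = 0L)
  }
  h <- op_lrelu(tape, op_conv3(tape, x, wt("ev.stem.w"), wt("ev.stem.b"), stride = 2L, pad = 1L))
  r <- op_conv3(tape, op_lrelu(tape, op_conv3(tape, h, wt("ev.r1a.w"), wt("ev.r1a.b"))),
                wt("ev.r1b.w"), wt("ev.r1b.b"))
  h <- op_lrelu(tape, op_add(tape, h, r))
  h <- op_lrelu(tape, op_conv3(tape, h, wt("ev.down.w"), wt("ev.down.b"), stride = 2L, pad = 1L))
  r <- op_conv3(tape, op_lrelu(tape, op_conv3(tape, h, wt("ev.r2a.w"), wt("ev.r2a.b"))),
                wt("ev.r2b.w"), wt("ev.r2b.b"))
  h <- op_lrelu(tape, op_add(tape, h, r))
  h <- op_gap(tape, h)
  h <- op_bias(tape, op_matmul(tape, h, wt("ev.head.W")), wt("ev.head.b"))
  # raw linear output: training targets are >= 0 and L1 keeps predictions in
  # range, while a saturating output head would kill gradients early on;
  # predictions are clipped at 0 only when reported
  op_mean(tape, h)
}

#' Train the similarity evaluator
#'
#' Minimizes the L1 error between the predicted and true spatial-error
#' magnitude over the sample set with Adam; deterministic under `seed`.
#'
#' @param samples list of `wm_evalsample` from [make_sample].
#' @param epochs passes over the sample set.
#' @param lr Adam learning rate.
#' @param seed seed controlling initialization and sample order.
#' @param cfg an [evaluator_config].
#' @param verbose print per-epoch mean loss.
#' @return Object of class `wm_evaluator` with elements `cfg`, `ps`
#'   (parameters), `history` (per-epoch mean L1), `meta`.
#' @export
train_evaluator <- function(samples, epochs = 6L, lr = 1e-3, seed = 1L,
                            cfg = evaluator_config(), verbose = FALSE) {
  if (length(samples) < 1L) stopf("need at least one sample")
  set.seed(seed)
  ps <- evaluator_params(cfg)
  st <- adam_state()
  t <- 0L
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    # step decay late in training for a stable final fit
    lr_ep <- lr * if (ep > 0.85 * epochs) 0.1 else if (ep > 0.6 * epochs) 0.3 else 1
    ord <- sample(length(samples))
    tot <- 0
    for (i in ord) {
      smp <- samples[[i]]
      tape <- ad_tape()
      x <- ad_input(tape, smp$input)
      pred <- evaluator_tape(tape, ps, cfg, x, trainable = TRUE)
      lossn <- op_abs(tape, op_cadd(tape, pred, -smp$target))
      ad_backward(tape, lossn)
      t <- t + 1L
      adam_step(ps, ad_grads(tape), st, lr_ep, t)
      tot <- tot + lossn$v
    }
    history[ep] <- tot / length(samples)
    if (verbose) message(sprintf("epoch %d: mean L1 %.4f", ep, history[ep]))
  }
  structure(list(cfg = cfg, ps = ps, history = history,
                 meta = list(epochs = epochs, lr = lr, seed = seed,
                             n_samples = length(samples))),
            class = "wm_evaluator")
}

#' Predict the spatial-error score for an image pair
#'
#' @param ev a trained `wm_evaluator`.
#' @param a,b 3D arrays or [wm_volume]s of the same shape (e.g. warped moving
#'   and fixed), intensities in \[0, 1\].
#' @return Non-negative scalar; lower means better spatial agreement.
#' @export
evaluator_predict <- function(ev, a, b) {
  stopifnot(inherits(ev, "wm_evaluator"))
  aa <- if (inherits(a, "wm_volume")) a$data else a
  bb <- if (inherits(b, "wm_volume")) b$data else b
  if (!all(dim(aa) == dim(bb))) stopf("shape mismatch")
  tape <- ad_tape()
  x <- ad_input(tape, array(c(aa, bb), dim = c(dim(aa), 2L)))
  max(0, evaluator_tape(tape, ev$ps, ev$cfg, x, trainable = FALSE)$v)
}

#' Similarity losses
#'
#' `similarity()` scores a warped/fixed pair with the trained evaluator
#' (lower is better). `ncc()` is the ablation baseline: one minus the mean
#' local (windowed) squared normalized cross-correlation, which is 0 for
#' identical images and invariant to affine intensity rescaling.
#'
#' @param ev a trained `wm_evaluator`.
#' @param warped,fixed 3D arrays or [wm_volume]s of the same shape.
#' @return Scalar loss (>= 0 for `ncc`).
#' @export
similarity <- function(ev, warped, fixed) evaluator_predict(ev, warped, fixed)

# Local NCC machinery shared by the plain and tape versions: box-filter
# moments with an eps that maps degenerate (flat) windows to correlation 1.
ncc_window <- function(shape, win) {
  w <- pmin(win, shape)
  w - (w + 1L) %% 2L            # make odd
}

#' @rdname similarity
#' @param win local window size (clamped per axis to the image, made odd).
#' @param eps stabilizer for flat windows.
#' @export
ncc <- function(warped, fixed, win = 9L, eps = 1e-8) {
  a <- if (inherits(warped, "wm_volume")) warped$data else warped
  b <- if (inherits(fixed, "wm_volume")) fixed$data else fixed
  if (!all(dim(a) == dim(b))) stopf("shape mismatch")
  d <- dim(a)
  w <- ncc_window(d, rep(win, length.out = 3L))
  # separable box sum: one 1-D convolution per axis
  raw <- function(x) {
    for (ax in 1:3) {
      kd <- c(1L, 1L, 1L); kd[ax] <- w[ax]
      pad <- c(0L, 0L, 0L); pad[ax] <- (w[ax] - 1L) %/% 2L
      ker <- array(1, dim = c(kd, 1L, 1L))
      x <- cpp_conv3_fwd(as.double(x), as.integer(c(d, 1L)), as.double(ker),
                         as.integer(dim(ker)), 0, c(1L, 1L, 1L), pad)
    }
    x
  }
  cnt <- raw(array(1, dim = d))            # local window size (shrinks at borders)
  box <- function(x) raw(x) / cnt
  mi <- box(a); mj <- box(b)
  cross <- box(a * b) - mi * mj
  vi <- pmax(box(a * a) - mi * mi, 0)
  vj <- pmax(box(b * b) - mj * mj, 0)
  cc <- (cross^2 + eps) / (vi * vj + eps)
  1 - mean(cc)
}

# Tape version of the local squared-NCC loss.
ncc_tape <- function(tape, a, b, win = 9L, eps = 1e-8) {
  d <- dim(a$v)[1:3]
  w <- ncc_window(d, rep(win, length.out = 3L))
  zb <- ad_input(tape, 0)
  kers <- lapply(1:3, function(ax) {
    kd <- c(1L, 1L, 1L); kd[ax] <- w[ax]
    ad_input(tape, array(1, dim = c(kd, 1L, 1L)))
  })
  pads <- lapply(1:3, function(ax) {
    p <- c(0L, 0L, 0L); p[ax] <- (w[ax] - 1L) %/% 2L; p
  })
  raw <- function(x) {
    for (ax in 1:3) x <- op_conv3(tape, x, kers[[ax]], zb, stride = 1L, pad = pads[[ax]])
    x
  }
  cnt_arr <- array(1, dim = c(d, 1L))
  for (ax in 1:3) {
    cnt_arr <- cpp_conv3_fwd(as.double(cnt_arr), as.integer(c(d, 1L)),
                             as.double(kers[[ax]]$v), as.integer(dim(kers[[ax]]$v)),
                             0, c(1L, 1L, 1L), as.integer(pads[[ax]]))
  }
  invcnt <- ad_input(tape, array(1 / cnt_arr, dim = c(d, 1L)))
  a4 <- op_reshape(tape, a, c(d, 1L))
  b4 <- op_reshape(tape, b, c(d, 1L))
  box <- function(x) op_mul(tape, raw(x), invcnt)
  mi <- box(a4); mj <- box(b4)
  cross <- op_sub(tape, box(op_mul(tape, a4, b4)), op_mul(tape, mi, mj))
  vi <- op_relu(tape, op_sub(tape, box(op_mul(tape, a4, a4)), op_mul(tape, mi, mi)))
  vj <- op_relu(tape, op_sub(tape, box(op_mul(tape, b4, b4)), op_mul(tape, mj, mj)))
  cc <- op_div(tape, op_cadd(tape, op_sq(tape, cross), eps),
               op_mul(tape, vi, vj), eps = eps)
  op_cadd(tape, op_smul(tape, op_mean(tape, cc), -1), 1)
}

# Tape version of the evaluator similarity (frozen parameters); a and b are
# 3D nodes.
similarity_tape <- function(tape, ev, a, b) {
  d <- dim(a$v)[1:3]
  a4 <- op_reshape(tape, a, c(d, 1L))
  b4 <- op_reshape(tape, b, c(d, 1L))
  x <- op_cat_last(tape, list(a4, b4))
  evaluator_tape(tape, ev$ps, ev$cfg, x, trainable = FALSE)
}

#' Save / load an evaluator as JSON (text) metadata plus parameters
#'
#' Parameters are flattened to plain numeric vectors in JSON, so checkpoints
#' are text files.
#'
#' @param ev a `wm_evaluator`.
#' @param path output `.json` path.
#' @return `path` invisibly, or the restored `wm_evaluator`.
#' @export
write_evaluator <- function(ev, path) {
  stopifnot(inherits(ev, "wm_evaluator"))
  pl <- ps_to_list(ev$ps)
  obj <- list(cfg = unclass(ev$cfg), meta = ev$meta, history = ev$history,
              params = lapply(pl, function(a) list(dim = dim(a) %||% length(a),
                                                   data = as.vector(a))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_evaluator
#' @export
read_evaluator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ps <- param_set()
  for (n in names(obj$params)) {
    ps[[n]] <- array(obj$params[[n]]$data, dim = obj$params[[n]]$dim)
  }
  class(ps) <- c("wm_params", class(ps))
  structure(list(cfg = structure(as.list(obj$cfg), class = "wm_evalconfig"),
                 ps = ps, history = obj$history, meta = obj$meta),
            class = "wm_evaluator")
}
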