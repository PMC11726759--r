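# Four-stage coarse-to-fine registration cascade. Stage inputs move from
# global to local and back: the coarsest stage aligns the low-frequency
# wavelet approximation (aaa), the two middle stages align the high-frequency
# enhancement image E, and the final stage aligns the original images. The
# accumulated displacement field is upsampled into each stage, the stage
# network refines it, and refinements are folded in by field composition.

#' Cascade configuration
#'
#' @param input_shape full-resolution grid (each axis divisible by 8 for the
#'   three-level wavelet decomposition and by the stage scales).
#' @param scales per-level grid scale, coarse to fine (default 1/8, 1/4, 1/2,
#'   1 of full resolution).
#' @param sources per-level input representation: `"aaa"` (low-frequency
#'   approximation), `"E"` (high-frequency enhancement) or `"original"`.
#' @param wavelet wavelet used for the subband inputs (default `db5`).
#' @param share_params use one parameter set for all levels instead of
#'   separate ones.
#' @param ... arguments forwarded to [net_config] for every level (e.g.
#'   `embed`, `depths`, `window`, `encoder`, `use_skip`).
#' @return Object of class `wm_cascadeconfig`; element `netcfgs` holds the
#'   per-level [net_config]s (coarse to fine, named level3..level0).
#' @export
cascade_config <- function(input_shape, scales = c(1 / 8, 1 / 4, 1 / 2, 1),
                           sources = c("aaa", "E", "E", "original"),
                           wavelet = "db5", share_params = FALSE, ...) {
  input_shape <- as.integer(input_shape)
  if (length(scales) != 4L || length(sources) != 4L) stopf("exactly 4 levels required")
  if (is.unsorted(scales)) stopf("levels must be ordered coarse to fine")
  if (!all(sources %in% c("aaa", "E", "original"))) stopf("invalid stage source")
  grids <- lapply(scales, function(s) {
    g <- input_shape * s
    if (any(abs(g - round(g)) > 1e-9)) stopf("scale %g does not divide the input shape", s)
    as.integer(round(g))
  })
  netcfgs <- lapply(grids, function(g) net_config(g, ...))
  names(netcfgs) <- paste0("level", 3:0)
  names(grids) <- names(netcfgs)
  structure(list(input_shape = input_shape, scales = scales, sources = sources,
                 grids = grids, wavelet = wavelet,
                 share_params = isTRUE(share_params), netcfgs = netcfgs),
            class = "wm_cascadeconfig")
}

#' @export
print.wm_cascadeconfig <- function(x, ...) {
  cat(sprintf("<wm_cascadeconfig input %s, wavelet %s>\n",
              paste(x$input_shape, collapse = "x"), x$wavelet))
  for (i in 1:4) {
    cat(sprintf("  level%d: %-8s grid %s\n", 4 - i, x$sources[i],
                paste(x$grids[[i]], collapse = "x")))
  }
  invisible(x)
}

#' Initialize the per-level networks of a cascade
#'
#' @param cfg a [cascade_config].
#' @param seed integer seed for reproducible initialization.
#' @return Named list of parameter sets (`level3`..`level0`); a single shared
#'   set is replicated by reference when `cfg$share_params`.
#' @export
cascade_nets <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$share_params) {
    ps <- sprnet_params(cfg$netcfgs[[1]])
    return(stats::setNames(rep(list(ps), 4L), names(cfg$netcfgs)))
  }
  stats::setNames(lapply(cfg$netcfgs, function(nc) sprnet_params(nc)),
                  names(cfg$netcfgs))
}

# Per-pair stage representations (plain arrays), computed once and reused
# across training iterations. Levels ordered coarse (level3) to fine.
cascade_reps <- function(fixed, moving, cfg) {
  prep <- function(vol) {
    arr <- minmax01(if (inherits(vol, "wm_volume")) vol$data else vol)
    tree <- dwt3_level(arr, cfg$wavelet, 3L)
    list(original = arr, aaa = tree[[3]]$bands$aaa,
         E = enhance_highfreq(tree[[1]])$data)
  }
  pf <- prep(fixed); pm <- prep(moving)
  lapply(seq_len(4L), function(i) {
    src <- cfg$sources[i]
    g <- cfg$grids[[i]]
    list(fixed = minmax01(resize_array(pf[[src]], g)),
         moving = minmax01(resize_array(pm[[src]], g)))
  })
}

#' Stage input representations
#'
#' Returns the configured representation of both images at one cascade
#' level's grid, min-max normalized: the level-3 `aaa` approximation for
#' global alignment, the enhancement image `E` for the local levels, or the
#' original intensities.
#'
#' @param fixed,moving [wm_volume]s on the same grid.
#' @param level cascade level, 3 (coarsest) to 0 (full resolution).
#' @param cfg a [cascade_config].
#' @return List with 3D arrays `fixed` and `moving` at the stage grid.
#' @export
stage_input <- function(fixed, moving, level, cfg) {
  if (!level %in% 0:3) stopf("level must be in 0..3")
  reps <- cascade_reps(fixed, moving, cfg)
  reps[[4L - level]]
}

# Forward pass of the whole cascade on a tape. Returns per-stage accumulated
# field nodes (at stage grids), refinement nodes, and the stage reps.
register_tape <- function(tape, cfg, nets, reps) {
  acc <- NULL
  stage_acc <- vector("list", 4L)
  stage_refine <- vector("list", 4L)
  for (i in seq_len(4L)) {
    lvname <- names(cfg$netcfgs)[i]
    nc <- cfg$netcfgs[[i]]
    g <- cfg$grids[[i]]
    fixed_node <- ad_input(tape, reps[[i]]$fixed)
    moving_arr <- reps[[i]]$moving
    if (is.null(acc)) {
      warped_node <- ad_input(tape, moving_arr)
      acc_up <- NULL
    } else {
      acc_up <- op_resize_field(tape, acc, g)
      mv4 <- ad_input(tape, array(moving_arr, dim = c(g, 1L)))
      warped_node <- op_reshape(tape, op_warp(tape, mv4, acc_up), g)
    }
    tape$wprefix <- if (cfg$share_params) "shared:" else paste0(lvname, ":")
    out <- sprnet_tape(tape, nets[[i]], nc, fixed_node, warped_node)
    tape$wprefix <- ""
    phi <- out$full
    if (is.null(acc_up)) {
      acc <- phi
    } else {
      # compose: refine-then-accumulate, result(x) = phi(x + acc(x)) + acc(x)
      warped_phi <- op_warp(tape, phi, acc_up)
      acc <- op_add(tape, warped_phi, acc_up)
    }
    stage_refine[[i]] <- phi
    stage_acc[[i]] <- acc
  }
  if (!all(cfg$grids[[4]] == cfg$input_shape)) {
    acc <- op_resize_field(tape, acc, cfg$input_shape)
  }
  list(final = acc, stage_acc = stage_acc, stage_refine = stage_refine)
}

#' Register a moving volume to a fixed volume
#'
#' Runs the four-stage cascade with the given per-level networks: stage
#' inputs are built from the wavelet representations, the accumulated field
#' is upsampled into each stage and refined by that stage's pyramid network,
#' and refinements are folded in by field composition. With freshly
#' initialized (zero-head) networks the result is the identity transform;
#' train with [fit_cascade] first.
#'
#' @param fixed,moving [wm_volume]s on the same grid (shape divisible by 8).
#' @param cfg a [cascade_config] matching the volume shape.
#' @param nets per-level parameter sets from [cascade_nets] (trained or not).
#' @return Object of class `wm_registration`: `field` (final full-resolution
#'   [wm_field]), `stage_fields` (accumulated field per stage, coarse to
#'   fine), `warped` (moving volume warped by `field`), `stage_inputs`.
#' @export
register <- function(fixed, moving, cfg, nets) {
  stopifnot(inherits(cfg, "wm_cascadeconfig"))
  fd <- if (inherits(fixed, "wm_volume")) dim(fixed$data) else dim(fixed)
  md <- if (inherits(moving, "wm_volume")) dim(moving$data) else dim(moving)
  if (!all(fd == md)) stopf("fixed and moving must share a grid (%s vs %s)",
                            paste(fd, collapse = "x"), paste(md, collapse = "x"))
  if (!all(fd == cfg$input_shape)) stopf("volume shape does not match cascade config")
  reps <- cascade_reps(fixed, moving, cfg)
  tape <- ad_tape()
  out <- register_tape(tape, cfg, nets, reps)
  field <- wm_field(out$final$v)
  mv <- if (inherits(moving, "wm_volume")) moving else wm_volume(moving)
  structure(list(field = field,
                 stage_fields = lapply(out$stage_acc, function(f) wm_field(f$v)),
                 warped = warp(mv, field),
                 stage_inputs = reps),
            class = "wm_registration")
}

#' @export
print.wm_registration <- function(x, ...) {
  jd <- jacobian_nonpositive_fraction(x$field)
  m <- sqrt(rowSums(matrix(x$field$vectors, ncol = 3L)^2))
  cat(sprintf("<wm_registration %s: 4 stages, |u| mean %.2f vox, JD<=0 %.3f%%>\n",
              paste(x$field$shape, collapse = "x"), mean(m), 100 * jd$fraction))
  invisible(x)
}
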