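# End-to-end cascade training: loss assembly (similarity + diffusion
# smoothness), the step-decay learning-rate schedule, and the Adam fitting
# loop with deep supervision across cascade stages.

#' Training configuration
#'
#' @param iterations optimizer iterations (the full-scale schedule runs
#'   15000; desk-scale runs use a few hundred).
#' @param base_lr initial learning rate (default 1e-4).
#' @param decay_factor multiplicative decay (default 0.6).
#' @param decay_every decay interval in iterations (default 1000).
#' @param decay_after iteration after which decay starts (default 5000).
#' @param similarity `"evaluator"` (the trained morphology-based evaluator)
#'   or `"ncc"` (local squared normalized cross-correlation ablation).
#' @param lambda weight of the diffusion (squared-gradient) smoothness
#'   penalty on the displacement field; 0 disables it.
#' @param deep_supervision apply the loss at every cascade stage (default)
#'   rather than only at the finest.
#' @param ncc_win local NCC window.
#' @param grad_clip global-norm gradient clipping threshold (0 disables);
#'   single-pair iterations have heavy-tailed gradients and clipping keeps
#'   the attention blocks stable.
#' @param ema Polyak decay for the returned parameters: the fitted model is
#'   an exponential moving average of the optimization iterates (0 disables).
#' @param seed RNG seed for the whole run.
#' @return Object of class `wm_trainconfig`.
#' @export
train_config <- function(iterations = 300L, base_lr = 1e-4, decay_factor = 0.6,
                         decay_every = 1000L, decay_after = 5000L,
                         similarity = c("evaluator", "ncc"), lambda = 1,
                         deep_supervision = TRUE, ncc_win = 9L, grad_clip = 1,
                         ema = 0.98, seed = 1L) {
  similarity <- match.arg(similarity)
  if (base_lr <= 0) stopf("learning rate must be > 0")
  if (lambda < 0) stopf("lambda must be >= 0")
  if (ema < 0 || ema >= 1) stopf("ema must be in [0, 1)")
  structure(list(iterations = as.integer(iterations), base_lr = base_lr,
                 decay_factor = decay_factor, decay_every = as.integer(decay_every),
                 decay_after = as.integer(decay_after), similarity = similarity,
                 lambda = lambda, deep_supervision = isTRUE(deep_supervision),
                 ncc_win = as.integer(ncc_win), grad_clip = grad_clip,
                 ema = ema, seed = as.integer(seed)),
            class = "wm_trainconfig")
}

#' Step-decay learning-rate schedule
#'
#' The base rate holds through `decay_after` iterations, then is multiplied
#' by `decay_factor` for every further block of `decay_every` iterations
#' (iterations `decay_after + 1 ... decay_after + decay_every` already run at
#' one decay step).
#'
#' @param iteration iteration number (>= 0).
#' @param cfg a [train_config].
#' @return The learning rate at that iteration.
#' @export
lr_schedule <- function(iteration, cfg = train_config()) {
  k <- pmax(0, ceiling((iteration - cfg$decay_after) / cfg$decay_every))
  cfg$base_lr * cfg$decay_factor^k
}

#' Diffusion smoothness penalty of a displacement field
#'
#' Mean squared forward difference of the field components over all axes
#' (quadratic in the field: doubling a field quadruples the penalty; zero
#' for any constant field).
#'
#' @param field a [wm_field] or H x W x L x 3 array.
#' @return Non-negative scalar.
#' @export
smoothness_penalty <- function(field) {
  u <- if (inherits(field, "wm_field")) field$vectors else field
  d <- dim(u)[1:3]
  tot <- 0; cnt <- 0
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    n <- d[ax]
    idx_a <- 2:n; idx_b <- 1:(n - 1)
    df <- switch(ax,
                 u[idx_a, , , , drop = FALSE] - u[idx_b, , , , drop = FALSE],
                 u[, idx_a, , , drop = FALSE] - u[, idx_b, , , drop = FALSE],
                 u[, , idx_a, , drop = FALSE] - u[, , idx_b, , drop = FALSE])
    tot <- tot + sum(df^2)
    cnt <- cnt + length(df)
  }
  if (cnt == 0) return(0)
  tot / cnt
}

# Tape version (custom fused backward).
op_smoothness <- function(tape, phi) {
  u <- phi$v
  d <- dim(u)[1:3]
  diffs <- vector("list", 3L); cnt <- 0
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    n <- d[ax]
    df <- switch(ax,
                 u[2:n, , , , drop = FALSE] - u[1:(n - 1), , , , drop = FALSE],
                 u[, 2:n, , , drop = FALSE] - u[, 1:(n - 1), , , drop = FALSE],
                 u[, , 2:n, , drop = FALSE] - u[, , 1:(n - 1), , drop = FALSE])
    diffs[[ax]] <- df
    cnt <- cnt + length(df)
  }
  val <- if (cnt == 0) 0 else sum(vapply(diffs[!vapply(diffs, is.null, TRUE)],
                                         function(x) sum(x^2), 1)) / cnt
  ad_push(tape, val, list(phi), function(nd) {
    g <- array(0, dim = dim(u))
    for (ax in 1:3) {
      df <- diffs[[ax]]
      if (is.null(df)) next
      gd <- 2 * df * nd$g / cnt
      n <- d[ax]
      if (ax == 1) {
        g[2:n, , , ] <- g[2:n, , , , drop = FALSE] + gd
        g[1:(n - 1), , , ] <- g[1:(n - 1), , , , drop = FALSE] - gd
      } else if (ax == 2) {
        g[, 2:n, , ] <- g[, 2:n, , , drop = FALSE] + gd
        g[, 1:(n - 1), , ] <- g[, 1:(n - 1), , , drop = FALSE] - gd
      } else {
        g[, , 2:n, ] <- g[, , 2:n, , drop = FALSE] + gd
        g[, , 1:(n - 1), ] <- g[, , 1:(n - 1), , drop = FALSE] - gd
      }
    }
    ad_acc(phi, g)
  })
}

#' Registration loss for a warped/fixed pair and its field
#'
#' Similarity term plus `lambda` times the diffusion smoothness of the field.
#'
#' @param warped,fixed 3D arrays or [wm_volume]s.
#' @param field a [wm_field].
#' @param cfg a [train_config].
#' @param evaluator trained `wm_evaluator` (required for
#'   `cfg$similarity == "evaluator"`).
#' @return Scalar loss.
#' @export
registration_loss <- function(warped, fixed, field, cfg = train_config(similarity = "ncc"),
                              evaluator = NULL) {
  sim <- if (cfg$similarity == "ncc") {
    ncc(warped, fixed, win = cfg$ncc_win)
  } else {
    if (is.null(evaluator)) stopf("evaluator similarity requires a trained evaluator")
    evaluator_predict(evaluator, warped, fixed)
  }
  sim + cfg$lambda * smoothness_penalty(field)
}

# Loss graph for one pair given precomputed stage reps.
cascade_loss_tape <- function(tape, ccfg, nets, reps, tcfg, evaluator) {
  fwd <- register_tape(tape, ccfg, nets, reps)
  stages <- if (tcfg$deep_supervision) seq_len(4L) else 4L
  total <- NULL
  parts <- list(sim = 0, smooth = 0)
  for (i in stages) {
    g <- ccfg$grids[[i]]
    acc <- fwd$stage_acc[[i]]
    mv4 <- ad_input(tape, array(reps[[i]]$moving, dim = c(g, 1L)))
    warped <- op_reshape(tape, op_warp(tape, mv4, acc), g)
    fixed_node <- ad_input(tape, reps[[i]]$fixed)
    # In evaluator mode the learned similarity scores the finest stage (the
    # original-intensity images it was trained on); the auxiliary
    # deep-supervision terms at the wavelet-representation stages use local
    # NCC, which is appropriate there because the enhancement/approximation
    # representations are shared across modalities.
    use_eval <- tcfg$similarity == "evaluator" && i == 4L
    sim <- if (use_eval) {
      similarity_tape(tape, evaluator, warped, fixed_node)
    } else {
      ncc_tape(tape, warped, fixed_node, win = tcfg$ncc_win)
    }
    stage_loss <- sim
    if (tcfg$lambda > 0) {
      stage_loss <- op_add(tape, stage_loss,
                           op_smul(tape, op_smoothness(tape, acc), tcfg$lambda))
    }
    parts$sim <- parts$sim + sim$v
    total <- if (is.null(total)) stage_loss else op_add(tape, total, stage_loss)
  }
  if (length(stages) > 1L) total <- op_smul(tape, total, 1 / length(stages))
  list(loss = total, sim = parts$sim / length(stages), final = fwd$final)
}

#' Train the registration cascade
#'
#' Joint unsupervised training of all four stage networks with Adam and the
#' step-decay schedule. Each iteration draws the next training pair (cyclic
#' order), rebuilds the forward graph, applies the similarity at every stage
#' (deep supervision) plus the smoothness penalty, and updates all
#' parameters. Deterministic under `cfg$seed`.
#'
#' @param pairs list of pairs; each element is a list with `fixed` and
#'   `moving` [wm_volume]s (e.g. from the phantom generator).
#' @param ccfg a [cascade_config].
#' @param nets per-level parameter sets from [cascade_nets]; updated in
#'   place and returned.
#' @param tcfg a [train_config].
#' @param evaluator trained `wm_evaluator` when
#'   `tcfg$similarity == "evaluator"`.
#' @param log_every record the loss every this many iterations (1 = all).
#' @param checkpoint_dir optional directory for parameter checkpoints.
#' @param checkpoint_every iterations between checkpoints (0 = only final).
#' @param verbose print progress.
#' @return List of class `wm_fit`: `nets`, `history` (data.frame with
#'   iteration, lr, loss, sim), `ccfg`, `tcfg`.
#' @export
fit_cascade <- function(pairs, ccfg, nets, tcfg = train_config(), evaluator = NULL,
                        log_every = 1L, checkpoint_dir = NULL, checkpoint_every = 0L,
                        verbose = FALSE) {
  if (length(pairs) < 1L) stopf("need at least one training pair")
  if (tcfg$similarity == "evaluator" && is.null(evaluator)) {
    stopf("evaluator similarity requires a trained evaluator")
  }
  set.seed(tcfg$seed)
  reps_cache <- lapply(pairs, function(p) cascade_reps(p$fixed, p$moving, ccfg))
  st <- adam_state()
  ema <- new.env(parent = emptyenv())
  hist <- list()
  for (it in seq_len(tcfg$iterations)) {
    reps <- reps_cache[[(it - 1L) %% length(pairs) + 1L]]
    tape <- ad_tape()
    out <- cascade_loss_tape(tape, ccfg, nets, reps, tcfg, evaluator)
    lv <- out$loss$v
    if (!is.finite(lv)) {
      stopf("training diverged at iteration %d (loss = %s); lower the learning rate",
            it, format(lv))
    }
    ad_backward(tape, out$loss)
    lr <- lr_schedule(it, tcfg)
    grads <- ad_grads(tape)
    if (tcfg$grad_clip > 0) {
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1)))
      if (is.finite(gnorm) && gnorm > tcfg$grad_clip) {
        sc <- tcfg$grad_clip / gnorm
        grads <- lapply(grads, function(g) g * sc)
      }
    }
    # qualified keys "<level>:<param>" map back to the per-level sets; Adam
    # state is keyed by qualified name so levels stay separate
    for (k in names(grads)) {
      lvname <- sub(":.*$", "", k)
      nm <- sub("^[^:]*:", "", k)
      ps <- if (lvname == "shared") nets[[1]] else nets[[lvname]]
      g <- grads[[k]]
      if (is.null(st[[k]])) st[[k]] <- list(m = 0 * g, v = 0 * g)
      s <- st[[k]]
      s$m <- 0.9 * s$m + 0.1 * g
      s$v <- 0.999 * s$v + 0.001 * g^2
      st[[k]] <- s
      mhat <- s$m / (1 - 0.9^it)
      vhat <- s$v / (1 - 0.999^it)
      ps[[nm]] <- ps[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      if (tcfg$ema > 0) {
        ema[[k]] <- if (is.null(ema[[k]])) ps[[nm]]
                    else tcfg$ema * ema[[k]] + (1 - tcfg$ema) * ps[[nm]]
      }
    }
    if (it %% log_every == 0L || it == 1L) {
      hist[[length(hist) + 1L]] <- data.frame(iteration = it, lr = lr,
                                              loss = lv, sim = out$sim)
    }
    if (!is.null(checkpoint_dir) && checkpoint_every > 0L && it %% checkpoint_every == 0L) {
      save_nets(nets, file.path(checkpoint_dir, sprintf("nets_iter%06d.json", it)), ccfg = ccfg)
    }
    if (verbose && (it %% 25L == 0L || it == 1L)) {
      message(sprintf("iter %4d  lr %.2e  loss %.5f  sim %.5f", it, lr, lv, out$sim))
    }
  }
  if (tcfg$ema > 0) {
    # the fitted model is the Polyak average of the iterates
    for (k in ls(ema)) {
      lvname <- sub(":.*$", "", k)
      nm <- sub("^[^:]*:", "", k)
      ps <- if (lvname == "shared") nets[[1]] else nets[[lvname]]
      ps[[nm]] <- ema[[k]]
    }
  }
  history <- do.call(rbind, hist)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    save_nets(nets, file.path(checkpoint_dir, "nets_final.json"), ccfg = ccfg)
    write.csv(history, file.path(checkpoint_dir, "loss_log.csv"), row.names = FALSE)
    # resolved run configuration, for reproducibility
    if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::write_yaml(unclass(tcfg), file.path(checkpoint_dir, "train_config.yaml"))
    } else {
      jsonlite::write_json(unclass(tcfg), file.path(checkpoint_dir, "train_config.json"),
                           auto_unbox = TRUE)
    }
  }
  structure(list(nets = nets, history = history, ccfg = ccfg, tcfg = tcfg),
            class = "wm_fit")
}

#' Save / load cascade networks as JSON text
#'
#' Parameters (and, when given, the cascade configuration needed to rebuild
#' the networks) are written as one JSON text file.
#'
#' @param nets named list of parameter sets.
#' @param path output `.json` path.
#' @param ccfg optional [cascade_config] serialized alongside the weights.
#' @return `path` invisibly, or for the reader a list of parameter sets with
#'   the configuration (if stored) in attribute `"config"`.
#' @export
save_nets <- function(nets, path, ccfg = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  params <- lapply(nets, function(ps) {
    pl <- ps_to_list(ps)
    lapply(pl, function(a) list(dim = dim(a) %||% length(a), data = as.vector(a)))
  })
  cfg <- if (!is.null(ccfg)) {
    list(input_shape = ccfg$input_shape, scales = ccfg$scales,
         sources = ccfg$sources, wavelet = ccfg$wavelet,
         share_params = ccfg$share_params)
  }
  jsonlite::write_json(list(params = params, config = cfg), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_nets
#' @export
load_nets <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  plists <- if (!is.null(obj$params)) obj$params else obj
  nets <- lapply(plists, function(pl) {
    ps <- param_set()
    for (n in names(pl)) ps[[n]] <- array(pl[[n]]$data, dim = pl[[n]]$dim)
    class(ps) <- c("wm_params", class(ps))
    ps
  })
  if (!is.null(obj$config)) attr(nets, "config") <- obj$config
  nets
}
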