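# Shared pyramid registration network: two independent hierarchical
# windowed-attention encoders (one per modality) and a shared convolutional
# pyramid decoder that predicts a coarse-to-fine stack of displacement
# fields. A CNN encoder variant is provided for ablations.

#' Network configuration
#'
#' Defines one pyramid registration network for a given input grid. The
#' encoder partitions the input into `patch`^3 blocks that are linearly
#' embedded to dimension `embed` (no positional embedding: registration is a
#' dense prediction task and any spatial misplacement is penalized by the
#' loss itself). Each encoder stage alternates window attention and
#' shifted-window attention blocks with pre-norm residual MLPs; patch merging
#' between stages halves the resolution (per axis where possible) and doubles
#' the channels, giving the D, 2D, 4D, 8D progression. Window extents are
#' clamped per axis to the feature grid so thin/coarse grids remain valid.
#'
#' @param input_shape integer length-3 grid the network operates on.
#' @param patch patch size K (each axis must be divisible by K).
#' @param embed embedding dimension D.
#' @param depths attention blocks per stage; `c(2, 2, 6, 2)` gives the
#'   full-scale 12-layer encoder, smaller settings suit desk-scale runs.
#' @param heads attention heads per stage.
#' @param window window size (voxels of the token grid).
#' @param mlp_ratio MLP hidden width / channels.
#' @param use_skip carry decoder hidden state across pyramid levels
#'   (skip-connection ablation switch).
#' @param encoder `"attention"` or `"cnn"` (ablation).
#' @return Object of class `wm_netconfig`.
#' @export
net_config <- function(input_shape, patch = 2L, embed = 16L,
                       depths = c(2L, 2L, 6L, 2L), heads = c(2L, 4L, 4L, 8L),
                       window = 4L, mlp_ratio = 2L, use_skip = TRUE,
                       encoder = c("attention", "cnn")) {
  encoder <- match.arg(encoder)
  input_shape <- as.integer(input_shape)
  embed <- as.integer(embed)
  window <- as.integer(window)
  depths <- as.integer(depths)
  heads <- as.integer(heads)
  # per-axis patch extent, clamped to the axis length (thin/coarse grids)
  patch <- pmin(as.integer(rep(patch, length.out = 3L)), input_shape)
  if (any(input_shape %% patch != 0L)) {
    ax <- which(input_shape %% patch != 0L)[1]
    stopf("input axis %d (%d) not divisible by patch size %d", ax, input_shape[ax], patch[ax])
  }
  nstages <- length(depths)
  if (length(heads) != nstages) stopf("heads must match depths in length")
  stages <- vector("list", nstages)
  g <- input_shape %/% patch
  ch <- as.integer(embed)
  for (s in seq_len(nstages)) {
    win <- vapply(g, function(d) {
      w <- min(window, d)
      while (d %% w != 0L) w <- w %/% 2L
      max(w, 1L)
    }, 1L)
    shift <- ifelse(win < g & win > 1L, win %/% 2L, 0L)
    stages[[s]] <- list(grid = g, channels = ch, win = as.integer(win),
                        shift = as.integer(shift), heads = as.integer(heads[s]),
                        depth = as.integer(depths[s]))
    if (s < nstages) {
      f <- ifelse(g %% 2L == 0L & g > 1L, 2L, 1L)
      stages[[s]]$merge_factor <- as.integer(f)
      g <- g %/% f
      ch <- 2L * ch
    }
  }
  structure(list(input_shape = input_shape, patch = as.integer(patch),
                 embed = as.integer(embed), depths = as.integer(depths),
                 heads = as.integer(heads), window = as.integer(window),
                 mlp_ratio = mlp_ratio, use_skip = isTRUE(use_skip),
                 encoder = encoder, nstages = nstages, stages = stages),
            class = "wm_netconfig")
}

#' @export
print.wm_netconfig <- function(x, ...) {
  cat(sprintf("<wm_netconfig %s encoder, input %s, patch %s, D %d, depths %s>\n",
              x$encoder, paste(x$input_shape, collapse = "x"),
              paste(x$patch, collapse = "x"), x$embed,
              paste(x$depths, collapse = "/")))
  for (s in seq_len(x$nstages)) {
    st <- x$stages[[s]]
    cat(sprintf("  stage %d: grid %s, C %d, win %s, heads %d\n", s,
                paste(st$grid, collapse = "x"), st$channels,
                paste(st$win, collapse = "x"), st$heads))
  }
  invisible(x)
}

# ---- parameters ------------------------------------------------------------

enc_prefixes <- c(moving = "em", fixed = "ef")

init_encoder_params <- function(ps, cfg, prefix) {
  K <- cfg$patch
  if (cfg$encoder == "attention") {
    ps_linear(ps, paste0(prefix, ".embed"), prod(K), cfg$embed)
    ps_layernorm(ps, paste0(prefix, ".embedln"), cfg$embed)
  } else {
    ps_conv(ps, paste0(prefix, ".embed"), K, 1L, cfg$embed)
  }
  for (s in seq_len(cfg$nstages)) {
    st <- cfg$stages[[s]]
    C <- st$channels
    for (b in seq_len(st$depth)) {
      p <- sprintf("%s.s%d.b%d", prefix, s, b)
      if (cfg$encoder == "attention") {
        ps_layernorm(ps, paste0(p, ".ln1"), C)
        ps_linear(ps, paste0(p, ".qkv"), C, 3L * C)
        ps_linear(ps, paste0(p, ".proj"), C, C)
        ps_layernorm(ps, paste0(p, ".ln2"), C)
        ps_linear(ps, paste0(p, ".fc1"), C, cfg$mlp_ratio * C)
        ps_linear(ps, paste0(p, ".fc2"), cfg$mlp_ratio * C, C)
      } else {
        ps_conv(ps, paste0(p, ".conv1"), 3L, C, C)
        ps_conv(ps, paste0(p, ".conv2"), 3L, C, C)
      }
    }
    if (s < cfg$nstages) {
      f <- st$merge_factor
      p <- sprintf("%s.m%d", prefix, s)
      if (cfg$encoder == "attention") {
        ps_layernorm(ps, paste0(p, "ln"), prod(f) * C)
        ps_linear(ps, paste0(p, "lin"), prod(f) * C, 2L * C)
      } else {
        ps_conv(ps, paste0(p, "conv"), f, C, 2L * C)
      }
    }
  }
}

init_decoder_params <- function(ps, cfg) {
  n <- cfg$nstages
  for (s in rev(seq_len(n))) {
    C <- cfg$stages[[s]]$channels
    cin <- 2L * C
    if (cfg$use_skip && s < n) cin <- cin + cfg$stages[[s + 1L]]$channels
    ps_conv(ps, sprintf("dec.h%d", s), 3L, cin, C)
    ps_conv(ps, sprintf("dec.phi%d", s), 3L, C, 3L, zero = TRUE)
  }
}

#' Initialize the parameters of a pyramid registration network
#'
#' Builds the two modality-specific encoders (independent parameters, shared
#' architecture) and the shared decoder. Field-prediction heads are
#' zero-initialized so an untrained network is exactly the identity
#' transform.
#'
#' @param cfg a [net_config].
#' @param seed optional integer seed for reproducible initialization.
#' @return A parameter environment (class `wm_params`).
#' @export
sprnet_params <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ps <- param_set()
  init_encoder_params(ps, cfg, enc_prefixes[["moving"]])
  init_encoder_params(ps, cfg, enc_prefixes[["fixed"]])
  init_decoder_params(ps, cfg)
  class(ps) <- c("wm_params", class(ps))
  ps
}

#' @export
print.wm_params <- function(x, ...) {
  cat(sprintf("<wm_params %d tensors, %d values>\n", length(ps_names(x)), ps_count(x)))
  invisible(x)
}

# ---- attention mechanics ---------------------------------------------------

.mask_cache <- new.env(parent = emptyenv())

# Attention mask [ws, ws, nw] for shifted windows: 0 within a contiguous
# region, -1e9 across regions (standard cyclic-shift masking).
window_mask <- function(grid, win, shift) {
  if (all(shift == 0L)) return(NULL)
  key <- paste(c(grid, win, shift), collapse = ",")
  m <- .mask_cache[[key]]
  if (!is.null(m)) return(m)
  region_ax <- function(a) {
    g <- grid[a]; w <- win[a]; s <- shift[a]
    id <- integer(g)
    if (s > 0L) {
      id[(g - w + 1L):g] <- 1L
      id[(g - s + 1L):g] <- 2L
    }
    id
  }
  ids <- array(0L, dim = grid)
  r1 <- region_ax(1); r2 <- region_ax(2); r3 <- region_ax(3)
  for (k in seq_len(grid[3])) for (j in seq_len(grid[2])) {
    ids[, j, k] <- r1 + 3L * r2[j] + 9L * r3[k]
  }
  ids <- roll_array(array(as.double(ids), dim = grid), -shift)
  nwin <- grid %/% win
  dim(ids) <- c(win[1], nwin[1], win[2], nwin[2], win[3], nwin[3])
  ids <- aperm(ids, c(1L, 3L, 5L, 2L, 4L, 6L))
  ws <- prod(win); nw <- prod(nwin)
  dim(ids) <- c(ws, nw)
  mask <- array(0, dim = c(ws, ws, nw))
  for (w in seq_len(nw)) {
    eq <- outer(ids[, w], ids[, w], `==`)
    mask[, , w] <- ifelse(eq, 0, -1e9)
  }
  .mask_cache[[key]] <- mask
  mask
}

# Partition an [g1,g2,g3,C] node into window-token cubes and back.
partition_windows <- function(tape, x, win, hd, nh) {
  g <- dim(x$v)[1:3]
  nwin <- g %/% win
  x <- op_reshape(tape, x, c(win[1], nwin[1], win[2], nwin[2], win[3], nwin[3], hd, nh))
  x <- op_aperm(tape, x, c(1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L))
  op_reshape(tape, x, c(prod(win), hd, prod(nwin) * nh))
}

unpartition_windows <- function(tape, x, grid, win, hd, nh) {
  nwin <- grid %/% win
  x <- op_reshape(tape, x, c(win[1], win[2], win[3], hd, nwin[1], nwin[2], nwin[3], nh))
  x <- op_aperm(tape, x, order(c(1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L)))
  op_reshape(tape, x, c(grid, hd * nh))
}

# One (shifted-)window multi-head self-attention sublayer on tokens [S, C].
wmsa <- function(tape, ps, prefix, x, st, shifted) {
  grid <- st$grid; C <- st$channels; nh <- st$heads
  hd <- C %/% nh
  win <- st$win
  shift <- if (shifted) st$shift else c(0L, 0L, 0L)
  y <- op_layernorm(tape, x, ad_weight(tape, ps, paste0(prefix, ".ln1.g")),
                    ad_weight(tape, ps, paste0(prefix, ".ln1.be")))
  if (any(shift > 0L)) {
    y <- op_reshape(tape, y, c(grid, C))
    y <- op_roll3(tape, y, -shift)
    y <- op_reshape(tape, y, c(prod(grid), C))
  }
  qkv <- op_bias(tape, op_matmul(tape, y, ad_weight(tape, ps, paste0(prefix, ".qkv.W"))),
                 ad_weight(tape, ps, paste0(prefix, ".qkv.b")))
  pieces <- lapply(1:3, function(i) {
    p <- op_slice_last(tape, qkv, (i - 1L) * C + 1L, i * C)
    p <- op_reshape(tape, p, c(grid, C))
    partition_windows(tape, p, win, hd, nh)
  })
  q <- pieces[[1]]; k <- pieces[[2]]; v <- pieces[[3]]
  scores <- op_smul(tape, op_bmm(tape, q, k, tB = TRUE), 1 / sqrt(hd))
  mask <- window_mask(grid, win, shift)
  if (!is.null(mask) && any(shift > 0L)) {
    nw <- prod(grid %/% win)
    full <- array(rep(as.vector(mask), nh), dim = c(dim(mask)[1:2], nw * nh))
    scores <- op_cadd(tape, scores, full)
  }
  attn <- op_softmax2(tape, scores)
  ctx <- op_bmm(tape, attn, v)
  ctx <- unpartition_windows(tape, ctx, grid, win, hd, nh)
  if (any(shift > 0L)) ctx <- op_roll3(tape, ctx, shift)
  ctx <- op_reshape(tape, ctx, c(prod(grid), C))
  op_bias(tape, op_matmul(tape, ctx, ad_weight(tape, ps, paste0(prefix, ".proj.W"))),
          ad_weight(tape, ps, paste0(prefix, ".proj.b")))
}

attn_block <- function(tape, ps, prefix, x, st, shifted) {
  x <- op_add(tape, x, wmsa(tape, ps, prefix, x, st, shifted))
  y <- op_layernorm(tape, x, ad_weight(tape, ps, paste0(prefix, ".ln2.g")),
                    ad_weight(tape, ps, paste0(prefix, ".ln2.be")))
  y <- op_bias(tape, op_matmul(tape, y, ad_weight(tape, ps, paste0(prefix, ".fc1.W"))),
               ad_weight(tape, ps, paste0(prefix, ".fc1.b")))
  y <- op_gelu(tape, y)
  y <- op_bias(tape, op_matmul(tape, y, ad_weight(tape, ps, paste0(prefix, ".fc2.W"))),
               ad_weight(tape, ps, paste0(prefix, ".fc2.b")))
  op_add(tape, x, y)
}

# ---- encoder forward -------------------------------------------------------

# Tokenize a volume node [H,W,L] into patch tokens [S, prod(K)]; K per axis.
tokenize_patches <- function(tape, x, K) {
  d <- dim(x$v)[1:3]
  n <- d %/% K
  x <- op_reshape(tape, x, c(K[1], n[1], K[2], n[2], K[3], n[3]))
  x <- op_aperm(tape, x, c(2L, 4L, 6L, 1L, 3L, 5L))
  op_reshape(tape, x, c(prod(n), prod(K)))
}

encode_tape <- function(tape, ps, cfg, x, prefix) {
  feats <- vector("list", cfg$nstages)
  if (cfg$encoder == "attention") {
    tok <- tokenize_patches(tape, x, cfg$patch)
    tok <- op_bias(tape, op_matmul(tape, tok, ad_weight(tape, ps, paste0(prefix, ".embed.W"))),
                   ad_weight(tape, ps, paste0(prefix, ".embed.b")))
    tok <- op_layernorm(tape, tok, ad_weight(tape, ps, paste0(prefix, ".embedln.g")),
                        ad_weight(tape, ps, paste0(prefix, ".embedln.be")))
    for (s in seq_len(cfg$nstages)) {
      st <- cfg$stages[[s]]
      for (b in seq_len(st$depth)) {
        tok <- attn_block(tape, ps, sprintf("%s.s%d.b%d", prefix, s, b), tok, st,
                          shifted = (b %% 2L == 0L))
      }
      feats[[s]] <- op_reshape(tape, tok, c(st$grid, st$channels))
      if (s < cfg$nstages) {
        f <- st$merge_factor
        g <- st$grid
        n2 <- g %/% f
        m <- op_reshape(tape, feats[[s]], c(f[1], n2[1], f[2], n2[2], f[3], n2[3], st$channels))
        m <- op_aperm(tape, m, c(2L, 4L, 6L, 1L, 3L, 5L, 7L))
        m <- op_reshape(tape, m, c(prod(n2), prod(f) * st$channels))
        p <- sprintf("%s.m%d", prefix, s)
        m <- op_layernorm(tape, m, ad_weight(tape, ps, paste0(p, "ln.g")),
                          ad_weight(tape, ps, paste0(p, "ln.be")))
        tok <- op_bias(tape, op_matmul(tape, m, ad_weight(tape, ps, paste0(p, "lin.W"))),
                       ad_weight(tape, ps, paste0(p, "lin.b")))
      }
    }
  } else {
    h <- op_reshape(tape, x, c(dim(x$v)[1:3], 1L))
    h <- op_conv3(tape, h, ad_weight(tape, ps, paste0(prefix, ".embed.w")),
                  ad_weight(tape, ps, paste0(prefix, ".embed.b")),
                  stride = cfg$patch, pad = 0L)
    h <- op_lrelu(tape, h)
    for (s in seq_len(cfg$nstages)) {
      st <- cfg$stages[[s]]
      for (b in seq_len(st$depth)) {
        p <- sprintf("%s.s%d.b%d", prefix, s, b)
        r <- op_conv3(tape, h, ad_weight(tape, ps, paste0(p, ".conv1.w")),
                      ad_weight(tape, ps, paste0(p, ".conv1.b")))
        r <- op_lrelu(tape, r)
        r <- op_conv3(tape, r, ad_weight(tape, ps, paste0(p, ".conv2.w")),
                      ad_weight(tape, ps, paste0(p, ".conv2.b")))
        h <- op_lrelu(tape, op_add(tape, h, r))
      }
      feats[[s]] <- h
      if (s < cfg$nstages) {
        f <- st$merge_factor
        p <- sprintf("%s.m%d", prefix, s)
        h <- op_lrelu(tape, op_conv3(tape, h, ad_weight(tape, ps, paste0(p, "conv.w")),
                                     ad_weight(tape, ps, paste0(p, "conv.b")),
                                     stride = f, pad = 0L))
      }
    }
  }
  feats
}

# ---- decoder forward -------------------------------------------------------

decode_tape <- function(tape, ps, cfg, fm, ff) {
  n <- cfg$nstages
  fields <- vector("list", n)
  h <- NULL
  phi <- NULL
  for (s in rev(seq_len(n))) {
    g <- cfg$stages[[s]]$grid
    if (s == n) {
      x <- op_cat_last(tape, list(fm[[s]], ff[[s]]))
    } else {
      phi_up <- op_resize_field(tape, phi, g)
      fmw <- op_warp(tape, fm[[s]], phi_up)
      inputs <- list(fmw, ff[[s]])
      if (cfg$use_skip) inputs <- c(inputs, list(op_resize3(tape, h, g)))
      x <- op_cat_last(tape, inputs)
    }
    h <- op_lrelu(tape, op_conv3(tape, x, ad_weight(tape, ps, sprintf("dec.h%d.w", s)),
                                 ad_weight(tape, ps, sprintf("dec.h%d.b", s))))
    delta <- op_conv3(tape, h, ad_weight(tape, ps, sprintf("dec.phi%d.w", s)),
                      ad_weight(tape, ps, sprintf("dec.phi%d.b", s)))
    phi <- if (s == n) delta else op_add(tape, phi_up, delta)
    fields[[n - s + 1L]] <- phi
  }
  fields
}

# Full network forward on the tape; returns stage fields (coarse -> fine) and
# the field upsampled to the input grid.
sprnet_tape <- function(tape, ps, cfg, fixed_node, moving_node) {
  fm <- encode_tape(tape, ps, cfg, moving_node, enc_prefixes[["moving"]])
  ff <- encode_tape(tape, ps, cfg, fixed_node, enc_prefixes[["fixed"]])
  fields <- decode_tape(tape, ps, cfg, fm, ff)
  full <- op_resize_field(tape, fields[[length(fields)]], cfg$input_shape)
  list(fields = fields, full = full)
}

# ---- user-facing wrappers --------------------------------------------------

#' Patch embedding of a volume
#'
#' Splits the volume into K^3 patches and linearly embeds each into a
#' D-dimensional token. No positional embedding is added, so the mapping is
#' equivariant under patch permutations.
#'
#' @param x 3D array or [wm_volume] with shape divisible by `cfg$patch`.
#' @param cfg a [net_config].
#' @param params parameters from [sprnet_params].
#' @param which which encoder's embedding to use.
#' @return S x D token matrix (S = prod(shape)/K^3).
#' @export
patch_embed <- function(x, cfg, params, which = c("moving", "fixed")) {
  which <- match.arg(which)
  arr <- if (inherits(x, "wm_volume")) x$data else x
  if (any(dim(arr) %% cfg$patch != 0L)) {
    ax <- base::which(dim(arr) %% cfg$patch != 0L)[1]
    stopf("axis %d (%d) not divisible by patch size %d", ax, dim(arr)[ax], cfg$patch[ax])
  }
  if (cfg$encoder != "attention") stopf("patch_embed applies to the attention encoder")
  tape <- ad_tape()
  pre <- enc_prefixes[[which]]
  tok <- tokenize_patches(tape, ad_input(tape, arr), cfg$patch)
  tok <- op_bias(tape, op_matmul(tape, tok, ad_weight(tape, params, paste0(pre, ".embed.W"))),
                 ad_weight(tape, params, paste0(pre, ".embed.b")))
  tok$v
}

#' Encode a volume into a feature pyramid
#'
#' @inheritParams patch_embed
#' @return List of class `wm_pyramid`: per-stage feature arrays
#'   (grid x channels), coarse last.
#' @export
encode <- function(x, cfg, params, which = c("moving", "fixed")) {
  which <- match.arg(which)
  arr <- if (inherits(x, "wm_volume")) x$data else x
  if (!all(dim(arr) == cfg$input_shape)) {
    stopf("volume shape %s does not match config input %s",
          paste(dim(arr), collapse = "x"), paste(cfg$input_shape, collapse = "x"))
  }
  tape <- ad_tape()
  feats <- encode_tape(tape, params, cfg, ad_input(tape, arr), enc_prefixes[[which]])
  structure(lapply(feats, function(f) f$v), class = "wm_pyramid")
}

#' Predict the coarse-to-fine field stack from two feature pyramids
#'
#' At the deepest level the concatenated modality features yield the coarsest
#' field; at each finer level the moving features are warped by the upsampled
#' accumulated field, concatenated with the fixed features (and the upsampled
#' decoder state when skips are enabled), and a 3x3x3 convolution head emits
#' the refinement that is added to the upsampled field.
#'
#' @param moving_feats,fixed_feats `wm_pyramid`s from [encode].
#' @param cfg a [net_config].
#' @param params parameters from [sprnet_params].
#' @return List of [wm_field]s, coarse to fine.
#' @export
decode_pyramid <- function(moving_feats, fixed_feats, cfg, params) {
  if (length(moving_feats) != cfg$nstages || length(fixed_feats) != cfg$nstages) {
    stopf("pyramid depth mismatch with config")
  }
  for (s in seq_len(cfg$nstages)) {
    if (!all(dim(moving_feats[[s]]) == dim(fixed_feats[[s]]))) {
      stopf("pyramid shape mismatch at stage %d", s)
    }
  }
  tape <- ad_tape()
  fm <- lapply(moving_feats, function(f) ad_input(tape, f))
  ff <- lapply(fixed_feats, function(f) ad_input(tape, f))
  fields <- decode_tape(tape, params, cfg, fm, ff)
  lapply(fields, function(f) wm_field(f$v))
}

#' One forward pass of the pyramid registration network
#'
#' @param fixed,moving 3D arrays or [wm_volume]s on the config grid.
#' @inheritParams decode_pyramid
#' @return List with `fields` (stage [wm_field]s, coarse to fine) and
#'   `field_full` (a [wm_field] at the input resolution).
#' @export
sprnet_apply <- function(fixed, moving, cfg, params) {
  fa <- if (inherits(fixed, "wm_volume")) fixed$data else fixed
  ma <- if (inherits(moving, "wm_volume")) moving$data else moving
  tape <- ad_tape()
  out <- sprnet_tape(tape, params, cfg, ad_input(tape, fa), ad_input(tape, ma))
  list(fields = lapply(out$fields, function(f) wm_field(f$v)),
       field_full = wm_field(out$full$v))
}
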