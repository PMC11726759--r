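# Minimal reverse-mode automatic differentiation on a linear tape. Nodes are
# environments holding a value, an accumulated gradient and a backward
# closure; the tape records creation order, which for the feed-forward graphs
# built here is already a topological order. Heavy kernels (3D convolution,
# trilinear sampling, batched matmul) run in C++.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t$wnodes <- list()
  t
}

ad_push <- function(tape, value, parents = list(), bfn = NULL, rq = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$parents <- parents
  nd$bfn <- bfn
  nd$rq <- if (is.null(rq)) any(vapply(parents, function(p) isTRUE(p$rq), TRUE)) else rq
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

# Constant / input leaf: no gradient flows into it.
ad_input <- function(tape, x) ad_push(tape, x, rq = FALSE)

# Trainable-parameter leaf. `key` must be unique within one tape (qualify it
# when several parameter sets share names); re-using an existing key returns
# the existing node so shared parameters accumulate gradient.
ad_weight <- function(tape, params, name, key = NULL) {
  key <- key %||% paste0(tape$wprefix %||% "", name)
  nd <- tape$wnodes[[key]]
  if (!is.null(nd)) {
    if (!identical(nd$v, params[[name]])) stopf("parameter key collision: '%s'", key)
    return(nd)
  }
  if (is.null(params[[name]])) stopf("unknown parameter '%s'", name)
  nd <- ad_push(tape, params[[name]], rq = TRUE)
  tape$wnodes[[key]] <- nd
  nd
}

ad_acc <- function(nd, g) {
  if (!isTRUE(nd$rq)) return(invisible(NULL))
  if (is.null(nd$g)) nd$g <- g else nd$g <- nd$g + g
  invisible(NULL)
}

# Backpropagate from a scalar node.
ad_backward <- function(tape, node) {
  node$g <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$bfn) && !is.null(nd$g) && isTRUE(nd$rq)) nd$bfn(nd)
  }
  invisible(NULL)
}

# Collect parameter gradients by name (zeros where a weight never received
# gradient, e.g. zero-initialized heads on the first pass).
ad_grads <- function(tape) {
  lapply(tape$wnodes, function(nd) {
    if (is.null(nd$g)) array(0, dim = dim(nd$v) %||% length(nd$v)) else nd$g
  })
}

dim0 <- function(x) dim(x) %||% length(x)

# ---- elementwise -----------------------------------------------------------

op_add <- function(tape, a, b) {
  ad_push(tape, a$v + b$v, list(a, b), function(nd) {
    ad_acc(a, nd$g); ad_acc(b, nd$g)
  })
}

op_sub <- function(tape, a, b) {
  ad_push(tape, a$v - b$v, list(a, b), function(nd) {
    ad_acc(a, nd$g); ad_acc(b, -nd$g)
  })
}

op_mul <- function(tape, a, b) {
  ad_push(tape, a$v * b$v, list(a, b), function(nd) {
    ad_acc(a, nd$g * b$v); ad_acc(b, nd$g * a$v)
  })
}

op_div <- function(tape, a, b, eps = 0) {
  den <- b$v + eps
  ad_push(tape, a$v / den, list(a, b), function(nd) {
    ad_acc(a, nd$g / den); ad_acc(b, -nd$g * a$v / den^2)
  })
}

# scalar constant multiply / add
op_smul <- function(tape, a, s) {
  ad_push(tape, a$v * s, list(a), function(nd) ad_acc(a, nd$g * s))
}

op_cadd <- function(tape, a, const) {
  ad_push(tape, a$v + const, list(a), function(nd) ad_acc(a, nd$g))
}

op_sq <- function(tape, a) {
  ad_push(tape, a$v^2, list(a), function(nd) ad_acc(a, 2 * a$v * nd$g))
}

op_abs <- function(tape, a) {
  ad_push(tape, abs(a$v), list(a), function(nd) ad_acc(a, sign(a$v) * nd$g))
}

op_sqrt <- function(tape, a, eps = 1e-12) {
  val <- sqrt(a$v + eps)
  ad_push(tape, val, list(a), function(nd) ad_acc(a, nd$g / (2 * val)))
}

op_relu <- function(tape, a) {
  m <- a$v > 0
  ad_push(tape, a$v * m, list(a), function(nd) ad_acc(a, nd$g * m))
}

op_lrelu <- function(tape, a, alpha = 0.2) {
  m <- ifelse(a$v > 0, 1, alpha)
  ad_push(tape, a$v * m, list(a), function(nd) ad_acc(a, nd$g * m))
}

op_gelu <- function(tape, a) {
  x <- a$v
  k <- sqrt(2 / pi)
  inner <- k * (x + 0.044715 * x^3)
  th <- tanh(inner)
  val <- 0.5 * x * (1 + th)
  ad_push(tape, val, list(a), function(nd) {
    dth <- (1 - th^2) * k * (1 + 3 * 0.044715 * x^2)
    ad_acc(a, nd$g * (0.5 * (1 + th) + 0.5 * x * dth))
  })
}

op_softplus <- function(tape, a) {
  x <- a$v
  val <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  ad_push(tape, val, list(a), function(nd) ad_acc(a, nd$g / (1 + exp(-x))))
}

# ---- shape -----------------------------------------------------------------

op_reshape <- function(tape, a, dm) {
  olddm <- dim0(a$v)
  v <- a$v
  dim(v) <- dm
  ad_push(tape, v, list(a), function(nd) {
    g <- nd$g
    dim(g) <- olddm
    ad_acc(a, g)
  })
}

op_aperm <- function(tape, a, perm) {
  inv <- order(perm)
  ad_push(tape, aperm(a$v, perm), list(a), function(nd) {
    ad_acc(a, aperm(nd$g, inv))
  })
}

# Concatenate along the LAST axis (contiguous in column-major storage).
op_cat_last <- function(tape, nodes) {
  dims <- lapply(nodes, function(n) dim0(n$v))
  lead <- dims[[1]][-length(dims[[1]])]
  lasts <- vapply(dims, function(d) d[length(d)], 1)
  sizes <- vapply(nodes, function(n) length(n$v), 1)
  val <- array(unlist(lapply(nodes, function(n) as.vector(n$v)), use.names = FALSE),
               dim = c(lead, sum(lasts)))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  ad_push(tape, val, nodes, function(nd) {
    g <- as.vector(nd$g)
    for (i in seq_along(nodes)) {
      gi <- g[starts[i]:ends[i]]
      dim(gi) <- dims[[i]]
      ad_acc(nodes[[i]], gi)
    }
  })
}

# Contiguous slice along the last axis (columns of a matrix, channels of a
# channel-last array).
op_slice_last <- function(tape, a, from, to) {
  d <- dim0(a$v)
  nlast <- d[length(d)]
  lead <- prod(d[-length(d)])
  v <- as.vector(a$v)[(lead * (from - 1) + 1):(lead * to)]
  dim(v) <- c(d[-length(d)], to - from + 1L)
  ad_push(tape, v, list(a), function(nd) {
    g <- array(0, dim = d)
    gv <- as.vector(g)
    gv[(lead * (from - 1) + 1):(lead * to)] <- as.vector(nd$g)
    dim(gv) <- d
    ad_acc(a, gv)
  })
}

# Cyclic shift along the first three axes of an [h,w,l,C] array.
roll_array <- function(x, sh) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    if (sh[a] %% d[a] == 0) seq_len(d[a])
    else 1L + (seq_len(d[a]) - 1L - sh[a]) %% d[a]
  })
  if (length(d) == 4L) x[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  else x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

op_roll3 <- function(tape, a, sh) {
  ad_push(tape, roll_array(a$v, sh), list(a), function(nd) {
    ad_acc(a, roll_array(nd$g, -sh))
  })
}

# ---- linear algebra --------------------------------------------------------

op_matmul <- function(tape, a, b) {
  ad_push(tape, a$v %*% b$v, list(a, b), function(nd) {
    if (isTRUE(a$rq)) ad_acc(a, nd$g %*% t(b$v))
    if (isTRUE(b$rq)) ad_acc(b, crossprod(a$v, nd$g))
  })
}

op_bias <- function(tape, a, b) {
  val <- sweep(a$v, 2L, b$v, `+`)
  ad_push(tape, val, list(a, b), function(nd) {
    ad_acc(a, nd$g)
    ad_acc(b, colSums(nd$g))
  })
}

# Batched matmul on cubes [r, k, B]; supports the two cases the attention
# blocks need.
op_bmm <- function(tape, a, b, tB = FALSE) {
  val <- cpp_bmm(a$v, b$v, FALSE, tB)
  ad_push(tape, val, list(a, b), function(nd) {
    if (tB) {
      if (isTRUE(a$rq)) ad_acc(a, cpp_bmm(nd$g, b$v, FALSE, FALSE))
      if (isTRUE(b$rq)) ad_acc(b, cpp_bmm(nd$g, a$v, TRUE, FALSE))
    } else {
      if (isTRUE(a$rq)) ad_acc(a, cpp_bmm(nd$g, b$v, FALSE, TRUE))
      if (isTRUE(b$rq)) ad_acc(b, cpp_bmm(a$v, nd$g, TRUE, FALSE))
    }
  })
}

# ---- normalization / softmax ----------------------------------------------

# Layer norm over the columns of an [n, C] matrix.
op_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$v
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  val <- sweep(sweep(xhat, 2L, gamma$v, `*`), 2L, beta$v, `+`)
  ad_push(tape, val, list(a, gamma, beta), function(nd) {
    g <- nd$g
    ad_acc(gamma, colSums(g * xhat))
    ad_acc(beta, colSums(g))
    dxhat <- sweep(g, 2L, gamma$v, `*`)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    ad_acc(a, istd * (dxhat - m1 - xhat * m2))
  })
}

# Softmax over the 2nd axis of a cube [r, c, B].
op_softmax2 <- function(tape, a) {
  d <- as.integer(dim(a$v))
  val <- cpp_softmax2_fwd(as.double(a$v), d)
  ad_push(tape, val, list(a), function(nd) {
    ad_acc(a, cpp_softmax2_bwd(as.double(val), as.double(nd$g), d))
  })
}

# ---- reductions ------------------------------------------------------------

op_mean <- function(tape, a) {
  n <- length(a$v)
  ad_push(tape, mean(a$v), list(a), function(nd) {
    ad_acc(a, array(nd$g / n, dim = dim0(a$v)))
  })
}

op_sum <- function(tape, a) {
  ad_push(tape, sum(a$v), list(a), function(nd) {
    ad_acc(a, array(nd$g, dim = dim0(a$v)))
  })
}

# Global average pool of [H,W,L,C] to [1, C].
op_gap <- function(tape, a) {
  d <- dim(a$v)
  n <- prod(d[1:3])
  m <- matrix(a$v, nrow = n)
  ad_push(tape, matrix(colMeans(m), nrow = 1L), list(a), function(nd) {
    g <- matrix(rep(as.vector(nd$g) / n, each = n), nrow = n)
    dim(g) <- d
    ad_acc(a, g)
  })
}

# ---- heavy kernels ---------------------------------------------------------

# 3D convolution; x [H,W,L,Ci] node, w/b weight nodes, zero padding.
op_conv3 <- function(tape, x, w, b, stride = 1L, pad = NULL) {
  wd <- dim(w$v)
  if (is.null(pad)) pad <- as.integer((wd[1:3] - 1L) / 2L)
  pad <- as.integer(rep(pad, length.out = 3L))
  stride <- as.integer(rep(stride, length.out = 3L))
  xd <- as.integer(dim(x$v))
  val <- cpp_conv3_fwd(as.double(x$v), xd, as.double(w$v), as.integer(wd),
                       as.double(b$v), stride, pad)
  ad_push(tape, val, list(x, w, b), function(nd) {
    res <- cpp_conv3_bwd(as.double(x$v), xd, as.double(w$v), as.integer(wd),
                         as.double(nd$g), stride, pad,
                         isTRUE(x$rq), isTRUE(w$rq))
    if (isTRUE(x$rq)) ad_acc(x, res$gx)
    if (isTRUE(w$rq)) ad_acc(w, res$gw)
    ad_acc(b, res$gb)
  })
}

# Trilinear sampling of x [H,W,L,C] at coords (node or constant n x 3 matrix);
# output [out_shape, C].
op_sample <- function(tape, x, coords, out_shape) {
  cmat <- if (is.environment(coords)) coords$v else coords
  xd <- as.integer(dim(x$v))
  val <- cpp_sample3(as.double(x$v), xd, cmat, FALSE)
  dim(val) <- c(out_shape, xd[4])
  parents <- if (is.environment(coords)) list(x, coords) else list(x)
  ad_push(tape, val, parents, function(nd) {
    g <- as.double(nd$g)
    if (isTRUE(x$rq)) {
      gx <- cpp_sample3_bwd_img(xd, cmat, g)
      dim(gx) <- dim(x$v)
      ad_acc(x, gx)
    }
    if (is.environment(coords) && isTRUE(coords$rq)) {
      ad_acc(coords, cpp_sample3_bwd_coords(as.double(x$v), xd, cmat, g))
    }
  })
}

# Warp feature map x [H,W,L,C] by displacement-field node phi [H,W,L,3]
# (voxel units); differentiable in both arguments.
op_warp <- function(tape, x, phi) {
  d <- dim(x$v)[1:3]
  n <- prod(d)
  phimat <- op_reshape(tape, phi, c(n, 3L))
  coords <- op_cadd(tape, phimat, identity_grid(d))
  op_sample(tape, x, coords, d)
}

# Trilinear resize of [H,W,L,C] features to a new spatial shape.
op_resize3 <- function(tape, x, out_shape) {
  if (all(dim(x$v)[1:3] == out_shape)) return(x)
  op_sample(tape, x, resize_coords(dim(x$v)[1:3], out_shape), out_shape)
}

# Resize a field node [h,w,l,3] to a new grid, rescaling components by the
# per-axis grid ratio (tape analogue of resize_field()).
op_resize_field <- function(tape, phi, out_shape) {
  old <- dim(phi$v)[1:3]
  if (all(old == out_shape)) return(phi)
  up <- op_resize3(tape, phi, out_shape)
  scale <- out_shape / old
  if (all(scale == scale[1])) return(op_smul(tape, up, scale[1]))
  sc <- array(1, dim = c(out_shape, 3L))
  for (a in 1:3) sc[, , , a] <- scale[a]
  op_mul(tape, up, ad_input(tape, sc))
}
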