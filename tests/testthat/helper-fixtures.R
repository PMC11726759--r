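# Shared fixtures and oracles for the test suite. Everything is generated in
# code; no binary files.

wm <- asNamespace("wavemorph")

# Constant displacement field on a grid.
const_field <- function(shape, t) {
  wm_field(array(rep(t, each = prod(shape)), dim = c(shape, 3L)))
}

# A smooth deterministic test volume (sum of separable cosines + blob).
smooth_volume <- function(shape, seed = 1) {
  set.seed(seed)
  d <- shape
  g <- wm$identity_grid(d)
  v <- cos(2 * pi * g[, 1] / d[1]) * 0.3 +
    sin(2 * pi * g[, 2] / d[2]) * 0.25 +
    cos(2 * pi * g[, 3] / max(d[3], 2)) * 0.2 +
    exp(-rowSums(sweep(g, 2, (d - 1) / 2)^2) / (0.1 * sum(d^2)))
  array(v - min(v), dim = d) / (max(v) - min(v))
}

# Brute-force grey-scale morphology oracle: per-voxel min/max over element
# offsets with replicate (clamped) borders. Independent nested-loop
# implementation.
brute_morph <- function(x, offsets, do_max) {
  d <- dim(x)
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    vals <- numeric(nrow(offsets))
    for (q in seq_len(nrow(offsets))) {
      ii <- min(max(i + offsets[q, 1], 1), d[1])
      jj <- min(max(j + offsets[q, 2], 1), d[2])
      kk <- min(max(k + offsets[q, 3], 1), d[3])
      vals[q] <- x[ii, jj, kk]
    }
    out[i, j, k] <- if (do_max) max(vals) else min(vals)
  }
  out
}

# Brute-force ASSD oracle: all-pairs nearest surface distances, 6-connectivity
# surfaces (volume border counts as outside).
brute_assd <- function(ma, mb, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    pts <- NULL
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      if (!m[i, j, k]) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else FALSE, if (i < d[1]) m[i + 1, j, k] else FALSE,
        if (j > 1) m[i, j - 1, k] else FALSE, if (j < d[2]) m[i, j + 1, k] else FALSE,
        if (k > 1) m[i, j, k - 1] else FALSE, if (k < d[3]) m[i, j, k + 1] else FALSE
      )
      if (length(nb) < 6 || !all(nb)) pts <- rbind(pts, c(i, j, k))
    }
    pts
  }
  sa <- surf(ma); sb <- surf(mb)
  mind <- function(p, q) {
    apply(p, 1, function(x) {
      min(sqrt(colSums((t(q) * spacing - x * spacing)^2)))
    })
  }
  dab <- mind(sa, sb); dba <- mind(sb, sa)
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

# Finite-difference gradient check of a scalar-valued tape graph w.r.t. one
# parameter array; returns max abs error over `k` random entries.
fd_gradcheck <- function(build, x0, eps = 1e-6, k = 8) {
  tape <- wm$ad_tape()
  ps <- wm$param_set()
  ps[["p"]] <- x0
  out <- build(tape, wm$ad_weight(tape, ps, "p"))
  wm$ad_backward(tape, out)
  ga <- tape$wnodes[["p"]]$g
  f <- function(xx) {
    t2 <- wm$ad_tape()
    ps2 <- wm$param_set()
    ps2[["p"]] <- xx
    build(t2, wm$ad_weight(t2, ps2, "p"))$v
  }
  idx <- sample(length(x0), min(k, length(x0)))
  errs <- vapply(idx, function(i) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    abs(ga[i] - (f(xp) - f(xm)) / (2 * eps))
  }, 1)
  max(errs)
}

# Small cascade configuration used across network tests.
tiny_cascade <- function(shape = c(32, 32, 8)) {
  cascade_config(shape, embed = 8, depths = c(1, 1, 1, 1), heads = c(2, 4, 4, 8),
                 window = 4)
}

# Mean DSC over the phantom organ labels.
mean_organ_dsc <- function(fixed_labels, other_labels, ids = 1:5) {
  mean(vapply(ids, function(id) dsc(fixed_labels, other_labels, id), 1))
}
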