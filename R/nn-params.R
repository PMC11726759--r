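# Parameter sets and the Adam optimizer. A parameter set is an environment
# mapping unique names to numeric arrays; initializers draw from the R RNG so
# whole-model setup is reproducible from one seed.

param_set <- function() new.env(parent = emptyenv())

ps_names <- function(ps) ls(ps, sorted = TRUE)

ps_add <- function(ps, name, value) {
  if (!is.null(ps[[name]])) stopf("parameter '%s' already exists", name)
  ps[[name]] <- value
  invisible(ps)
}

ps_count <- function(ps) sum(vapply(ps_names(ps), function(n) length(ps[[n]]), 1))

# Linear layer W [nin, nout] + b [nout]; truncated-normal-ish init (sd 0.02)
# as is conventional for attention blocks; zero init for field heads.
ps_linear <- function(ps, name, nin, nout, zero = FALSE, sd = 0.02) {
  W <- if (zero) array(0, dim = c(nin, nout))
       else array(rnorm(nin * nout, sd = sd), dim = c(nin, nout))
  ps_add(ps, paste0(name, ".W"), W)
  ps_add(ps, paste0(name, ".b"), numeric(nout))
}

# Conv layer w [k0,k1,k2,ci,co] + b [co]; He init scaled by fan-in.
ps_conv <- function(ps, name, k, ci, co, zero = FALSE) {
  k <- rep(k, length.out = 3L)
  fan <- prod(k) * ci
  w <- if (zero) array(0, dim = c(k, ci, co))
       else array(rnorm(prod(k) * ci * co, sd = sqrt(2 / fan)), dim = c(k, ci, co))
  ps_add(ps, paste0(name, ".w"), w)
  ps_add(ps, paste0(name, ".b"), numeric(co))
}

ps_layernorm <- function(ps, name, dim) {
  ps_add(ps, paste0(name, ".g"), rep(1, dim))
  ps_add(ps, paste0(name, ".be"), numeric(dim))
}

# Serialize a parameter set (plain list, suitable for saveRDS or JSON-free
# binary-free reconstruction).
ps_to_list <- function(ps) {
  stats::setNames(lapply(ps_names(ps), function(n) ps[[n]]), ps_names(ps))
}

ps_from_list <- function(lst) {
  ps <- param_set()
  for (n in names(lst)) ps[[n]] <- lst[[n]]
  ps
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(ps, grads, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (n in names(grads)) {
    g <- grads[[n]]
    if (is.null(st[[n]])) st[[n]] <- list(m = 0 * g, v = 0 * g)
    s <- st[[n]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    st[[n]] <- s
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    ps[[n]] <- ps[[n]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(ps)
}
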