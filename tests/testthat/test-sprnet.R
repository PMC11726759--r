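test_that("patch embedding yields HWL/K^3 tokens and no positional term", {
  cfg <- net_config(c(8, 8, 8), patch = 2, embed = 8, depths = c(1, 1),
                    heads = c(2, 2), window = 2)
  ps <- sprnet_params(cfg, seed = 1)
  v <- array(rnorm(8^3), dim = c(8, 8, 8))
  tok <- patch_embed(v, cfg, ps)
  expect_equal(dim(tok), c(64L, 8L))

  # zero volume: every token equals the embedding bias
  tok0 <- patch_embed(array(0, dim = c(8, 8, 8)), cfg, ps)
  expect_lt(max(abs(sweep(tok0, 2, ps[["em.embed.b"]]))), 1e-12)

  # permutation equivariance: shuffling patches shuffles tokens identically
  # (shift the volume by one full patch along x == rotating token blocks)
  v2 <- v[c(3:8, 1:2), , ]
  tok2 <- patch_embed(v2, cfg, ps)
  grid_idx <- array(seq_len(64), dim = c(4, 4, 4))  # token grid 4x4x4, x fastest
  shifted <- grid_idx[c(2:4, 1), , ]
  expect_equal(tok2, tok[as.vector(shifted), ])

  expect_error(patch_embed(array(0, dim = c(7, 8, 8)), cfg, ps), "axis 1")
})

test_that("the encoder follows the configured channel and window progression", {
  cfg <- net_config(c(32, 32, 32), patch = 2, embed = 8, depths = c(1, 1, 1, 1),
                    heads = c(2, 4, 4, 8), window = 4)
  expect_equal(vapply(cfg$stages, function(s) s$channels, 1L), c(8L, 16L, 32L, 64L))
  expect_equal(vapply(cfg$stages, function(s) paste(s$grid, collapse = "x"), ""),
               c("16x16x16", "8x8x8", "4x4x4", "2x2x2"))
  # a 16^3 feature map with window 8 is split into 2x2x2 = 8 windows
  cfg8 <- net_config(c(32, 32, 32), patch = 2, embed = 8, depths = c(1, 1),
                     heads = c(2, 2), window = 8)
  expect_equal(prod(cfg8$stages[[1]]$grid %/% cfg8$stages[[1]]$win), 8)

  ps <- sprnet_params(cfg, seed = 2)
  v <- smooth_volume(c(32, 32, 32), seed = 3)
  pyr <- encode(v, cfg, ps, "moving")
  expect_length(pyr, 4)
  for (s in 1:4) {
    expect_equal(dim(pyr[[s]]), c(cfg$stages[[s]]$grid, cfg$stages[[s]]$channels))
  }
  # independent encoders: same volume, different features
  pyr_f <- encode(v, cfg, ps, "fixed")
  expect_gt(max(abs(pyr[[1]] - pyr_f[[1]])), 1e-6)
})

test_that("the decoder is the identity at zero-head init and doubles field shapes", {
  cfg <- net_config(c(16, 16, 8), patch = 2, embed = 8, depths = c(1, 1, 1),
                    heads = c(2, 2, 4), window = 2)
  ps <- sprnet_params(cfg, seed = 4)
  v1 <- smooth_volume(c(16, 16, 8), seed = 5)
  v2 <- smooth_volume(c(16, 16, 8), seed = 6)
  fields <- decode_pyramid(encode(v1, cfg, ps, "moving"), encode(v2, cfg, ps, "fixed"),
                           cfg, ps)
  expect_length(fields, 3)
  # identical inputs + zero-initialized heads: all fields exactly zero
  expect_true(all(vapply(fields, function(f) max(abs(f$vectors)) == 0, TRUE)))
  # per-axis shapes double coarse -> fine
  shapes <- t(vapply(fields, function(f) f$shape, c(1L, 1L, 1L)))
  expect_equal(shapes[2, ], shapes[1, ] * 2L)
  expect_equal(shapes[3, ], shapes[2, ] * 2L)

  out <- sprnet_apply(v2, v1, cfg, ps)
  expect_equal(out$field_full$shape, c(16L, 16L, 8L))
  expect_equal(max(abs(out$field_full$vectors)), 0)

  # mismatched pyramids are rejected
  short <- encode(v1, cfg, ps, "moving")[1:2]
  expect_error(decode_pyramid(short, encode(v2, cfg, ps, "fixed"), cfg, ps), "depth")
})

test_that("skip connections and the encoder kind change the prediction", {
  mk <- function(use_skip, encoder) {
    net_config(c(16, 16, 8), patch = 2, embed = 8, depths = c(1, 1),
               heads = c(2, 2), window = 2, use_skip = use_skip, encoder = encoder)
  }
  v1 <- smooth_volume(c(16, 16, 8), seed = 7)
  v2 <- smooth_volume(c(16, 16, 8), seed = 8)
  run <- function(cfg, seed) {
    ps <- sprnet_params(cfg, seed = seed)
    # non-zero heads so architectural differences are visible
    set.seed(seed + 100)
    for (nm in grep("^dec\\.phi", wm$ps_names(ps), value = TRUE)) {
      ps[[nm]] <- array(rnorm(length(ps[[nm]]), sd = 0.05), dim = dim(ps[[nm]]) %||% length(ps[[nm]]))
    }
    sprnet_apply(v2, v1, cfg, ps)$field_full$vectors
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  a <- run(mk(TRUE, "attention"), 9)
  b <- run(mk(FALSE, "attention"), 9)
  expect_gt(max(abs(a - b)), 1e-8)

  # the CNN-encoder ablation honours the same decode contract
  cfgc <- mk(TRUE, "cnn")
  psc <- sprnet_params(cfgc, seed = 10)
  outc <- sprnet_apply(v2, v1, cfgc, psc)
  expect_equal(outc$field_full$shape, c(16L, 16L, 8L))
  expect_equal(max(abs(outc$field_full$vectors)), 0)
  pyrc <- encode(v1, cfgc, psc, "moving")
  expect_equal(dim(pyrc[[2]])[4], 16L)
})

test_that("the forward pass is deterministic for fixed parameters", {
  cfg <- net_config(c(16, 16, 8), patch = 2, embed = 8, depths = c(1, 1),
                    heads = c(2, 2), window = 4)
  ps <- sprnet_params(cfg, seed = 11)
  v1 <- smooth_volume(c(16, 16, 8), seed = 12)
  v2 <- smooth_volume(c(16, 16, 8), seed = 13)
  p1 <- encode(v1, cfg, ps, "moving")
  p2 <- encode(v1, cfg, ps, "moving")
  expect_identical(p1[[2]], p2[[2]])
  # same seed, same parameters
  ps2 <- sprnet_params(cfg, seed = 11)
  expect_identical(ps[["em.s1.b1.qkv.W"]], ps2[["em.s1.b1.qkv.W"]])
  expect_identical(encode(v1, cfg, ps2, "moving")[[1]], p1[[1]])
})
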