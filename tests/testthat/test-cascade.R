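test_that("stage inputs follow the configured sources, grids and normalization", {
  cc <- tiny_cascade(c(32, 32, 8))
  p <- generate_pair(phantom_spec(shape = c(32, 32, 8), seed = 51))
  si3 <- stage_input(p$fixed, p$moving, 3, cc)
  expect_equal(dim(si3$fixed), c(4L, 4L, 1L))    # 1/8 of 32x32x8
  si0 <- stage_input(p$fixed, p$moving, 0, cc)
  expect_equal(dim(si0$fixed), dim(p$fixed$data))
  expect_equal(range(si0$fixed), c(0, 1))
  # levels 2 and 1 are enhancement-derived: non-negative by construction
  for (lv in c(2, 1)) {
    si <- stage_input(p$fixed, p$moving, lv, cc)
    expect_true(min(si$fixed) >= 0 && min(si$moving) >= 0)
    expect_equal(dim(si$fixed), as.integer(c(32, 32, 8) * cc$scales[4 - lv]))
  }
  expect_error(stage_input(p$fixed, p$moving, 4, cc), "level")
  # the level-3 aaa grid of a full-scale 384x256x32 volume is 48x32x4
  cc_full <- cascade_config(c(384, 256, 32), embed = 8, depths = c(1, 1),
                            heads = c(2, 2), window = 4)
  expect_equal(cc_full$grids[["level3"]], c(48L, 32L, 4L))
})

test_that("an untrained cascade is the identity and records 4 stage fields", {
  cc <- tiny_cascade(c(32, 32, 8))
  nets <- cascade_nets(cc, seed = 52)
  p <- generate_pair(phantom_spec(shape = c(32, 32, 8), seed = 53))
  reg <- register(p$fixed, p$moving, cc, nets)
  expect_s3_class(reg, "wm_registration")
  expect_length(reg$stage_fields, 4)
  expect_equal(max(abs(reg$field$vectors)), 0)
  expect_equal(reg$warped$data, p$moving$data)
  expect_equal(reg$field$shape, c(32L, 32L, 8L))
  # moving == fixed also maps to the identity
  reg2 <- register(p$fixed, p$fixed, cc, nets)
  expect_equal(max(abs(reg2$field$vectors)), 0)

  expect_error(register(p$fixed, wm_volume(array(0, dim = c(16, 16, 8))), cc, nets),
               "grid")
})

test_that("cascade configuration validates level structure", {
  expect_error(cascade_config(c(32, 32, 8), scales = c(1, 1 / 2, 1 / 4, 1 / 8)),
               "coarse to fine")
  expect_error(cascade_config(c(32, 32, 8), sources = c("aaa", "foo", "E", "original")),
               "invalid")
  expect_error(cascade_config(c(30, 32, 8)), "divide")
  cc <- cascade_config(c(32, 32, 8), share_params = TRUE, embed = 8,
                       depths = c(1, 1), heads = c(2, 2), window = 2)
  nets <- cascade_nets(cc, seed = 54)
  expect_identical(nets[[1]], nets[[4]])
})

test_that("a trained tiny cascade recovers a known translation", {
  # moving = fixed anatomy shifted by (+2, 0, 0) voxels, same modality; a
  # short training run must align most of the shift (|mean u - 2| < 0.5)
  d <- c(16L, 16L, 8L)
  base <- smooth_volume(d, seed = 55)
  fixed <- wm_volume(base)
  moving <- wm_volume(warp(base, const_field(d, c(-2, 0, 0))))  # content shifted -x
  cc <- cascade_config(d, embed = 8, depths = c(1, 1), heads = c(2, 2), window = 2)
  nets <- cascade_nets(cc, seed = 56)
  tc <- train_config(iterations = 80, base_lr = 2e-3, similarity = "ncc",
                     lambda = 0.5, ncc_win = 7, seed = 57)
  fit <- fit_cascade(list(list(fixed = fixed, moving = moving)), cc, nets, tc)
  reg <- register(fixed, moving, cc, nets)
  # interior mean x-displacement should approach +2 (sampling moving at x+2
  # recovers the fixed image)
  ux <- reg$field$vectors[5:12, 5:12, 3:6, 1]
  expect_lt(abs(mean(ux) - 2), 0.5)
  # and the similarity must have improved over the identity
  expect_lt(ncc(reg$warped$data, fixed$data, win = 7),
            ncc(moving$data, fixed$data, win = 7))
})
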