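test_that("the learning-rate schedule holds then decays by 0.6 per 1000 iterations", {
  tc <- train_config()
  expect_equal(lr_schedule(0, tc), 1e-4)
  expect_equal(lr_schedule(1, tc), 1e-4)
  expect_equal(lr_schedule(5000, tc), 1e-4)
  expect_equal(lr_schedule(5999, tc), 1e-4 * 0.6)
  expect_equal(lr_schedule(6000, tc), 1e-4 * 0.6)
  expect_equal(lr_schedule(7000, tc), 1e-4 * 0.6^2)
  expect_equal(lr_schedule(15000, tc), 1e-4 * 0.6^10)
  expect_error(train_config(base_lr = 0), "learning rate")
  expect_error(train_config(lambda = -1), "lambda")
})

test_that("the loss vanishes for aligned pairs and is quadratic in the field", {
  v <- smooth_volume(c(12, 12, 8), seed = 72)
  d <- c(12L, 12L, 8L)
  tc <- train_config(similarity = "ncc", lambda = 5)
  expect_lt(registration_loss(v, v, zero_field(d), tc), 1e-9)

  expect_equal(smoothness_penalty(zero_field(d)), 0)
  set.seed(73)
  u <- array(rnorm(prod(d) * 3), dim = c(d, 3L))
  s1 <- smoothness_penalty(wm_field(u))
  s2 <- smoothness_penalty(wm_field(2 * u))
  expect_equal(s2 / s1, 4, tolerance = 1e-12)
  # constant fields carry no smoothness penalty
  expect_equal(smoothness_penalty(const_field(d, c(2, -1, 3))), 0)
})

test_that("training is deterministic under a fixed seed and logs its history", {
  d <- c(16L, 16L, 8L)
  p <- generate_pair(phantom_spec(shape = d, seed = 74))
  cc <- cascade_config(d, embed = 8, depths = c(1, 1), heads = c(2, 2), window = 2)
  tc <- train_config(iterations = 5, base_lr = 1e-3, similarity = "ncc", seed = 75)
  run <- function() {
    nets <- cascade_nets(cc, seed = 76)
    fit_cascade(list(list(fixed = p$fixed, moving = p$moving)), cc, nets, tc)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history$loss, f2$history$loss)
  expect_equal(nrow(f1$history), 5)
  expect_true(all(c("iteration", "lr", "loss", "sim") %in% names(f1$history)))
  # parameters changed from their initialization
  nets0 <- cascade_nets(cc, seed = 76)
  expect_gt(max(abs(f1$nets[[1]][["dec.phi1.w"]] - nets0[[1]][["dec.phi1.w"]])), 0)
})

test_that("an identical-pair dataset keeps the loss at zero in NCC mode", {
  d <- c(16L, 16L, 8L)
  v <- wm_volume(smooth_volume(d, seed = 77))
  cc <- cascade_config(d, embed = 8, depths = c(1, 1), heads = c(2, 2), window = 2)
  nets <- cascade_nets(cc, seed = 78)
  tc <- train_config(iterations = 3, similarity = "ncc", lambda = 1, seed = 79)
  fit <- fit_cascade(list(list(fixed = v, moving = v)), cc, nets, tc)
  # identical images + zero-init identity transform: loss starts (and stays) ~0
  expect_lt(max(abs(fit$history$loss)), 1e-6)
})

test_that("network checkpoints round-trip through JSON text", {
  cc <- cascade_config(c(16, 16, 8), embed = 8, depths = c(1, 1), heads = c(2, 2),
                       window = 2)
  nets <- cascade_nets(cc, seed = 80)
  p <- tempfile(fileext = ".json")
  save_nets(nets, p, ccfg = cc)
  nets2 <- load_nets(p)
  expect_equal(names(nets2), names(nets))
  expect_equal(nets2[["level0"]][["em.s1.b1.qkv.W"]], nets[["level0"]][["em.s1.b1.qkv.W"]],
               tolerance = 1e-12)
  cfg <- attr(nets2, "config")
  expect_equal(as.integer(cfg$input_shape), c(16L, 16L, 8L))
  expect_equal(cfg$sources, c("aaa", "E", "E", "original"))
})
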