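test_that("encoder block halves spatial dims and applies the stated pipeline", {
  set.seed(21)
  expect_equal(dim(encoderBlock(array(rnorm(64 * 64), c(1, 64, 64, 1)), 20)),
               c(1L, 32L, 32L, 20L))
  expect_equal(dim(encoderBlock(array(rnorm(300), c(1, 10, 10, 3)), 5)),
               c(1L, 5L, 5L, 5L))
  # zero weights with identity batch-norm (inference stats 0/1) -> all zero
  x <- array(rnorm(8 * 8 * 2), c(1, 8, 8, 2))
  out <- encoderBlock(x, 4, params = zero_encoder_params(2L, 4L))
  expect_equal(max(abs(out)), 0)
  expect_error(encoderBlock(array(1, c(2, 4, 4, 1)), 4), "batch size 1")
})

test_that("decoder block doubles dims, concatenates skips, and is nonnegative", {
  set.seed(22)
  x <- array(rnorm(15 * 10 * 320) * 0.1, c(1, 15, 10, 320))
  skip <- array(rnorm(30 * 20 * 160) * 0.1, c(1, 30, 20, 160))
  p <- init_decoder_params(320L, 160L, layerHyperParams())
  out <- decoderBlock(x, list(skip), 160, params = p)
  expect_equal(dim(out), c(1L, 30L, 20L, 320L))
  expect_gte(min(out), 0)
  # inference determinism: dropout is disabled
  expect_identical(out, decoderBlock(x, list(skip), 160, params = p))
  # training mode applies dropout stochastically
  set.seed(1); a <- decoderBlock(x, list(skip), 160, params = p, training = TRUE)
  set.seed(2); b <- decoderBlock(x, list(skip), 160, params = p, training = TRUE)
  expect_false(identical(a, b))
  bad_skip <- array(0, c(1, 29, 20, 8))
  expect_error(decoderBlock(x, list(bad_skip), 160, params = p), "twice")
})

test_that("residual block is F(h) + h with an exact zero-branch identity", {
  set.seed(23)
  h <- array(rnorm(15 * 10 * 12), c(1, 15, 10, 12))
  expect_equal(residualBlock(h, params = zero_residual_params(12L)), h)
  p <- init_residual_params(12L, layerHyperParams())
  out <- residualBlock(h, params = p)
  expect_equal(dim(out), dim(h))
  # out - h equals the branch computed standalone on the same tape ops
  tp <- new_tape()
  st <- new.env()
  pn <- wrap_params(tp, p)
  f <- tp_conv2d(tp, tp_leaf(tp, fm_in(h)), pn$W1, pn$b1, 1L)
  f <- tp_batchnorm(tp, f, pn$gamma1, pn$beta1, st, "a", FALSE)
  f <- tp_conv2d(tp, f, pn$W2, pn$b2, 1L)
  f <- tp_batchnorm(tp, f, pn$gamma2, pn$beta2, st, "b", FALSE)
  expect_equal(out - h, fm_out(f$value))
  expect_error(residualBlock(h, filters = 320), "channels")
})

test_that("residual stack preserves shape and composes identities", {
  set.seed(24)
  h <- array(rnorm(15 * 10 * 6), c(1, 15, 10, 6))
  zp <- replicate(4, zero_residual_params(6L), simplify = FALSE)
  expect_equal(residualStack(h, n = 4, params = zp), h)
  expect_equal(dim(residualStack(h, n = 4)), dim(h))
  p1 <- list(init_residual_params(6L, layerHyperParams()))
  expect_equal(residualStack(h, n = 1, params = p1),
               residualBlock(h, params = p1[[1]]))
})

test_that("attention gate reproduces the hand-computed scalar case", {
  # x = 1, g = 0, W_x = 2, W_g = 3, b_g = 0, psi = 1, b_psi = 0:
  # q = relu(2) * 1 = 2, alpha = 1 / (1 + e^-2)
  x <- array(1, c(1, 2, 2, 1))
  g <- array(0, c(1, 1, 1, 1))
  p <- list(Wx = array(2, c(1, 1, 1, 1)), Wg = array(3, c(1, 1, 1, 1)),
            b_g = 0, psi = array(1, c(1, 1, 1, 1)), b_psi = 0)
  out <- attentionGate(x, g, params = p, upsample_mode = "nearest")
  expect_equal(as.vector(out$alpha), rep(1 / (1 + exp(-2)), 4))
  expect_equal(out$alpha[1, 1, 1, 1], 0.88080, tolerance = 1e-4)
  expect_equal(out$gated, x * (1 / (1 + exp(-2))))
})

test_that("attention coefficients are strictly inside (0,1); zero psi gives x/2", {
  set.seed(25)
  x <- array(rnorm(8 * 6 * 5), c(1, 8, 6, 5))
  g <- array(rnorm(4 * 3 * 7), c(1, 4, 3, 7))
  out <- attentionGate(x, g)
  expect_true(all(out$alpha > 0 & out$alpha < 1))
  expect_equal(dim(out$alpha), c(1L, 8L, 6L, 1L))
  p0 <- init_attention_params(5L, 7L, 2L, layerHyperParams())
  p0$psi[] <- 0; p0$b_psi <- 0
  out0 <- attentionGate(x, g, params = p0)
  expect_equal(as.vector(out0$alpha), rep(0.5, 48))
  expect_equal(out0$gated, x / 2)
  expect_error(attentionGate(x, array(0, c(1, 3, 3, 2))), "half")
})

test_that("output head doubles dims, saturates to (0,1), and is 0.5 at zero weights", {
  set.seed(26)
  x <- array(rnorm(6 * 4 * 20), c(1, 6, 4, 20))
  out <- outputHead(x)
  expect_equal(dim(out), c(1L, 12L, 8L, 1L))
  expect_true(all(out > 0 & out < 1))
  p0 <- list(K = array(0, c(5, 5, 1, 20)), b = 0)
  expect_equal(as.vector(outputHead(x, params = p0)), rep(0.5, 96))
})

test_that("a single network runs the full encoder/bottleneck/gated-decoder chain", {
  cfg <- tiny_config()
  net <- buildSingleNet(cfg, seed = 5)
  x <- matrix(rnorm(64 * 32), 64, 32)
  r <- forwardSingleNet(net, x)
  expect_equal(dim(r$out), c(1L, 64L, 32L, 1L))
  expect_true(all(r$out > 0 & r$out < 1))
  expect_length(r$ags, 4L)
  # encoder halves dims at every level; channels follow the filter list
  expect_equal(lapply(r$encoder_dims, function(d) d[1:2]),
               list(c(32L, 16L), c(16L, 8L), c(8L, 4L), c(4L, 2L), c(2L, 1L)))
  expect_equal(vapply(r$encoder_dims, `[`, integer(1), 3L),
               cfg@encoder_filters)
  # attention-gated skips sit at the matching encoder scales (deepest first)
  expect_equal(lapply(r$ags, function(a) dim(a)[2:4]),
               list(c(4L, 2L, 5L), c(8L, 4L, 4L), c(16L, 8L, 3L), c(32L, 16L, 2L)))
  expect_error(forwardSingleNet(net, matrix(0, 60, 32)), "divisible")
})

test_that("the double network couples the two templates as specified", {
  cfg <- tiny_config()
  model <- assembleDoubleNet(cfg, seed = 9)
  x <- matrix(rnorm(32 * 32), 32, 32)
  pr <- predictPair(model, x)
  expect_s4_class(pr, "PredictionPair")
  expect_equal(dim(salientMap(pr)), c(32L, 32L))
  expect_equal(dim(segmentationMap(pr)), c(32L, 32L))
  expect_true(all(segmentationMap(pr) > 0 & segmentationMap(pr) < 1))
  # net2 decoder consumes the gated skips of BOTH networks: its deconv
  # kernels expect deconv-filters + 2 x gated channels from the level above
  ef <- cfg@encoder_filters; df <- cfg@decoder_filters
  for (k in 2:4) {
    cin2 <- dim(get(paste0("dec", k, ".K"), envir = model@net2@params))[4]
    expect_equal(cin2, df[k - 1] + 2L * ef[length(ef) - (k - 1)])
    cin1 <- dim(get(paste0("dec", k, ".K"), envir = model@net1@params))[4]
    expect_equal(cin1, df[k - 1] + ef[length(ef) - (k - 1)])
  }
})

test_that("parameter count matches the closed-form layer walk and is seed-invariant", {
  cfg <- tiny_config()
  m1 <- assembleDoubleNet(cfg, seed = 1)
  m2 <- assembleDoubleNet(cfg, seed = 2)
  expect_identical(countParameters(m1), countParameters(m2))
  expect_equal(countParameters(m1@net1), layer_walk_count(cfg))
  expect_equal(countParameters(m1@net2), layer_walk_count(cfg, dual_skips = TRUE))
  # hand arithmetic spot checks: 5x5 conv 1->20 with bias, and a 20-channel bn
  p <- init_encoder_params(1L, 20L, layerHyperParams())
  expect_equal(length(p$W) + length(p$b), 5 * 5 * 1 * 20 + 20)
  expect_equal(length(p$gamma) + length(p$beta), 40)
})

test_that("assembly and forward passes are deterministic under a fixed seed", {
  cfg <- tiny_config()
  m1 <- assembleDoubleNet(cfg, seed = 42)
  m2 <- assembleDoubleNet(cfg, seed = 42)
  nm <- ls(m1@net1@params)
  expect_identical(lapply(nm, get, envir = m1@net1@params),
                   lapply(nm, get, envir = m2@net1@params))
  x <- matrix(rnorm(32 * 32), 32, 32)
  p1 <- predictPair(m1, x); p2 <- predictPair(m2, x)
  expect_identical(segmentationMap(p1), segmentationMap(p2))
  expect_identical(salientMap(p1), salientMap(p2))
})
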