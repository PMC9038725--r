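test_that("training is reproducible and logs a bounded objective", {
  samples <- make_synth_samples(4, seed = 71)
  cfg <- tiny_config()
  model <- assembleDoubleNet(cfg, seed = 71)
  tc <- trainConfig(epochs = 3L, seed = 5L)
  f1 <- trainModel(model, samples, tc)
  f2 <- trainModel(model, samples, tc)
  expect_identical(f1$log, f2$log)
  expect_equal(nrow(f1$log), 3L)
  lam <- tc@aux_loss_weight
  expect_true(all(f1$log$train_loss >= -(1 + lam) & f1$log$train_loss <= 0))
  expect_true(all(f1$log$train_dice >= 0 & f1$log$train_dice <= 1))
  # the input model is untouched; the returned copy differs
  expect_identical(model@net1@params$enc1.W,
                   assembleDoubleNet(cfg, seed = 71)@net1@params$enc1.W)
  expect_false(identical(f1$model@net1@params$enc1.W,
                         model@net1@params$enc1.W))
})

test_that("one optimization step moves parameters in every layer group of both nets", {
  # 64 x 64 keeps the bottleneck at 2 x 2; a 1 x 1 bottleneck would make
  # spatial batch-norm degenerate and block gradients by construction
  samples <- make_synth_samples(1, seed = 72, height = 64L, width = 64L)
  model <- assembleDoubleNet(tiny_config(), seed = 72)
  fit <- trainModel(model, samples, trainConfig(epochs = 1L, seed = 1L))
  groups <- c(paste0("enc", 1:5), paste0("res", 1:4), paste0("ag", 1:4),
              paste0("dec", 1:4), "head")
  for (net in c("net1", "net2")) {
    p0 <- slot(model, net)@params
    p1 <- slot(fit$model, net)@params
    for (g in groups) {
      nms <- grep(paste0("^", g, "\\."), ls(p0), value = TRUE)
      delta <- max(vapply(nms, function(nm)
        max(abs(get(nm, envir = p1) - get(nm, envir = p0))), numeric(1)))
      expect_gt(delta, 0)
    }
  }
})

test_that("validation logging and best-epoch selection work on a held-out split", {
  samples <- make_synth_samples(5, seed = 73)
  split <- splitDataset(samples, 0.2, seed = 1)
  model <- assembleDoubleNet(tiny_config(), seed = 73)
  fit <- trainModel(model, split, trainConfig(epochs = 2L, seed = 1L))
  expect_true(all(is.finite(fit$log$val_dice)))
  expect_true(all(fit$log$val_loss >= -1 & fit$log$val_loss <= 0))
  expect_equal(fit$log$val_loss, -fit$log$val_dice)
})

test_that("padded prediction restores the original frame exactly", {
  model <- assembleDoubleNet(tiny_config(), seed = 74)
  img <- matrix(rnorm(100 * 60), 100, 60)    # pads internally to 128 x 64
  pr <- predictSegmentation(model, img)
  expect_equal(dim(segmentationMap(pr$pred)), c(100L, 60L))
  expect_equal(dim(salientMap(pr$pred)), c(100L, 60L))
  expect_equal(dim(pr$mask), c(100L, 60L))
  expect_true(all(pr$mask %in% c(0, 1)))
  # a zero-logit output head produces 0.5 everywhere -> all-ones mask
  z <- copy_model(model)
  z@net2@params$head.K[] <- 0
  z@net2@params$head.b[] <- 0
  przz <- predictSegmentation(z, img)
  expect_equal(max(abs(segmentationMap(przz$pred) - 0.5)), 0)
  expect_true(all(przz$mask == 1))
})

test_that("evaluation aggregates per-sample metrics independently of order", {
  samples <- make_synth_samples(4, seed = 75)
  model <- assembleDoubleNet(tiny_config(), seed = 75)
  rep1 <- evaluateModel(model, samples)
  expect_equal(rep1@n, 4L)
  per <- perSampleMetrics(rep1)
  expect_equal(metricSummary(rep1)$mean[1], mean(per$dsc))
  expect_equal(metricSummary(rep1)$sd[2], sd(per$jsc))
  rep2 <- evaluateModel(model, rev(samples))
  expect_equal(sort(perSampleMetrics(rep2)$dsc), sort(per$dsc))
  expect_equal(metricSummary(rep2)$mean, metricSummary(rep1)$mean)
})

test_that("checkpoints round-trip bit-exactly and reject mismatched templates", {
  model <- assembleDoubleNet(tiny_config(), seed = 76)
  img <- matrix(rnorm(32 * 32), 32, 32)
  before <- predictPair(model, img)
  f <- tempfile(fileext = ".bin")
  saveCheckpoint(model, f, epoch = 17L, seed = 76L)
  back <- loadCheckpoint(f)
  expect_identical(attr(back, "epoch"), 17L)
  expect_identical(attr(back, "seed"), 76L)
  after <- predictPair(back, img)
  expect_identical(segmentationMap(after), segmentationMap(before))
  expect_identical(salientMap(after), salientMap(before))
  # explicit template check
  expect_s4_class(loadCheckpoint(f, config = tiny_config()), "DoubleNetModel")
  expect_error(loadCheckpoint(f, config = reduced_config()), "does not match")
  expect_error(loadCheckpoint(tempfile()), "not found")
})

test_that("training states its abort diagnostic on non-finite losses", {
  samples <- make_synth_samples(1, seed = 77)
  model <- assembleDoubleNet(tiny_config(), seed = 77)
  model@net1@params$enc1.W[] <- NaN
  expect_error(trainModel(model, samples, trainConfig(epochs = 1L)),
               "non-finite loss")
})
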