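test_that("soft Dice matches hand-computed overlaps", {
  t1 <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(softDice(t1, t1), 1, tolerance = 1e-6)
  # disjoint supports leave only the smoothing term
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(softDice(a, b), 1e-6 / (4 + 1e-6))
  # 2x2: pred 0.5 everywhere, target half-filled -> 2*1 / (2+2)
  expect_equal(softDice(matrix(0.5, 2, 2), matrix(c(1, 1, 0, 0), 2)), 0.5,
               tolerance = 1e-6)
  expect_error(softDice(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("the minus-Dice loss spans [-1, 0] and mirrors softDice", {
  set.seed(31)
  t1 <- random_mask(8, 8)
  expect_equal(diceLoss(t1, t1), -1, tolerance = 1e-6)
  p <- matrix(runif(64), 8)
  expect_identical(diceLoss(p, t1), -softDice(p, t1))
  expect_gte(diceLoss(p, t1), -1)
  expect_lte(diceLoss(p, t1), 0)
})

test_that("dice loss strictly decreases as predictions interpolate toward the target", {
  set.seed(32)
  tgt <- random_mask(16, 16, 0.4)
  p0 <- matrix(runif(256), 16)
  losses <- vapply(seq(0, 1, by = 0.1),
                   function(a) diceLoss((1 - a) * p0 + a * tgt, tgt), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_equal(losses[11], -1, tolerance = 1e-5)
})

test_that("hard Dice and Jaccard match set-counting on the worked 2x2 case", {
  a <- matrix(0, 2, 2); a[1, 1] <- 1; a[1, 2] <- 1
  b <- matrix(0, 2, 2); b[1, 2] <- 1; b[2, 2] <- 1
  expect_equal(hardDice(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(hardDice(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  z <- matrix(0, 2, 2)
  expect_equal(hardDice(z, z), 1)   # both-empty convention
  expect_equal(jaccard(z, z), 1)
  expect_equal(hardDice(a, z), 0)
  expect_error(hardDice(a, matrix(0.5, 2, 2)), "0 or 1")
})

test_that("contour extraction returns 4-neighborhood boundaries", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  ct <- extractContour(m)
  expect_equal(ct, matrix(c(3L, 3L), 1), ignore_attr = TRUE)
  full <- matrix(1, 3, 3)
  ct3 <- extractContour(full)
  expect_equal(nrow(ct3), 8L)          # all but the center
  expect_false(any(ct3[, 1] == 2 & ct3[, 2] == 2))
  e <- extractContour(matrix(0, 4, 4))
  expect_equal(nrow(e), 0L)
  expect_true(attr(e, "empty"))
})

test_that("Hausdorff distance matches hand-computed geometry", {
  expect_equal(hausdorffDistance(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  # directed asymmetry: a -> b is 0, b -> a is 10
  expect_equal(hausdorffDistance(rbind(c(0, 0)),
                                 rbind(c(0, 0), c(10, 0))), 10)
  ct <- extractContour(matrix(1, 3, 3))
  expect_equal(hausdorffDistance(ct, ct), 0)
  expect_equal(hausdorffDistance(rbind(c(0, 0)), rbind(c(3, 4)), spacing = 0.5),
               2.5)
  expect_error(hausdorffDistance(matrix(numeric(0), 0, 2), rbind(c(1, 1))),
               "undefined")
})

test_that("metrics agree exactly with naive oracles on random mask pairs", {
  set.seed(33)
  for (i in 1:100) {
    a <- random_mask(16, 16, runif(1, 0.1, 0.6))
    b <- random_mask(16, 16, runif(1, 0.1, 0.6))
    expect_identical(hardDice(a, b), oracle_dsc(a, b))
    expect_identical(jaccard(a, b), oracle_jsc(a, b))
    # symmetry and bounds
    expect_identical(hardDice(a, b), hardDice(b, a))
    expect_identical(jaccard(a, b), jaccard(b, a))
    d <- hardDice(a, b)
    expect_true(d >= 0 && d <= 1)
    # Dice/Jaccard identity
    expect_equal(jaccard(a, b), d / (2 - d), tolerance = 1e-12)
    ca <- extractContour(a); cb <- extractContour(b)
    if (nrow(ca) > 0 && nrow(cb) > 0) {
      hd <- hausdorffDistance(ca, cb)
      expect_equal(hd, oracle_hausdorff(ca, cb))
      expect_identical(hd, hausdorffDistance(cb, ca))
    }
  }
})

test_that("binarization uses the >= threshold tie rule and is idempotent", {
  p <- matrix(c(0.49, 0.5, 0.51, 0.1), 2)
  out <- binarize(p)
  expect_equal(as.vector(out), c(0, 1, 1, 0))
  expect_identical(binarize(out), out)
  expect_equal(as.vector(binarize(p, 0.2)), c(1, 1, 1, 0))
  expect_error(binarize(p, 1), "threshold")
})

test_that("metric reports aggregate correctly and round-trip through CSV", {
  rep <- metricReport(c("a", "b", "c"), dsc = c(0.9, 0.8, 0.7),
                      jsc = c(0.8, 0.7, 0.6), hd = c(2, NA, 4))
  expect_equal(rep@summary$mean, c(0.8, 0.7, 3))
  expect_equal(rep@summary$sd[1], sd(c(0.9, 0.8, 0.7)))
  expect_equal(rep@hd_undefined, 1L)
  # single sample: SD reported as 0
  one <- metricReport("a", 0.9, 0.8, 1)
  expect_equal(one@summary$sd, c(0, 0, 0))
  f <- tempfile(fileext = ".csv")
  writeMetricReport(rep, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 5L)              # 3 samples + mean + sd footer
  expect_equal(tab$dsc[tab$id == "mean"], 0.8)
})
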