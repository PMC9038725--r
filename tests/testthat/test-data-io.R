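make_png <- function(values01, path, color = FALSE) {
  img <- if (color) EBImage::Image(values01, colormode = "Color")
         else EBImage::Image(t(values01))
  EBImage::writeImage(img, path)
  path
}

test_that("loading converts RGB to luminance and thresholds masks at >127", {
  d <- withr::local_tempdir()
  # 2x1 RGB: pure red and pure white (EBImage layout is x, y, channel)
  a <- array(0, c(2, 1, 3)); a[1, 1, ] <- c(1, 0, 0); a[2, 1, ] <- 1
  make_png(a, file.path(d, "img.png"), color = TRUE)
  make_png(matrix(c(127, 128) / 255, nrow = 1), file.path(d, "mask.png"))
  s <- loadSample(file.path(d, "img.png"), file.path(d, "mask.png"), id = "t")
  expect_equal(dim(sampleImage(s)), c(1L, 2L))
  expect_equal(as.vector(sampleImage(s)), c(76, 255))   # round(0.299 * 255), white
  expect_equal(as.vector(sampleMask(s)), c(0, 1))       # 127 -> 0, 128 -> 1
  make_png(matrix(0.5, 3, 3), file.path(d, "bad.png"))
  expect_error(loadSample(file.path(d, "img.png"), file.path(d, "bad.png")),
               "mismatch")
  expect_error(loadSample(file.path(d, "nope.png"), file.path(d, "mask.png")),
               "cannot read")
})

test_that("8-bit image values round-trip through save and load", {
  d <- withr::local_tempdir()
  m <- matrix(sample(0:255, 24, replace = TRUE), 4, 6)
  make_png(m / 255, file.path(d, "g.png"))
  make_png(matrix(1, 4, 6), file.path(d, "m.png"))
  s <- loadSample(file.path(d, "g.png"), file.path(d, "m.png"))
  expect_equal(sampleImage(s), m)
})

test_that("standardization is an exact population z-score with guarded degenerate case", {
  r <- standardizeImage(c(1, 2, 3))
  expect_equal(r$image, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(r$params$s, sqrt(2 / 3))
  set.seed(41)
  img <- matrix(runif(100, 0, 255), 10)
  z <- standardizeImage(img)$image
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-6)
  # affine intensity invariance (positive gain)
  expect_equal(standardizeImage(3 * img + 40)$image, z, tolerance = 1e-6)
  expect_equal(standardizeImage(matrix(7, 4, 4))$image, matrix(0, 4, 4))
})

test_that("resizing keeps masks binary and honors nearest pixel-center mapping", {
  m4 <- matrix(0, 4, 4); m4[1:2, 1:2] <- 1
  s <- segmentationSample(m4 * 100, m4, "t")
  r <- resizePair(s, width = 2, height = 2)
  expect_equal(sampleMask(r), matrix(c(1, 0, 0, 0), 2))
  expect_true(all(sampleMask(r) %in% c(0, 1)))
  expect_identical(resizePair(s, width = 4, height = 4), s)   # identity
  set.seed(42)
  big <- segmentationSample(matrix(runif(64 * 48), 48, 64),
                            random_mask(48, 64), "u")
  rb <- resizePair(big, width = 32, height = 24)
  expect_equal(dim(sampleImage(rb)), c(24L, 32L))   # height x width layout
  expect_true(all(sampleMask(rb) %in% c(0, 1)))
})

test_that("the seeded split partitions 612 samples into 490/122", {
  samples <- as.list(seq_len(612))
  sp <- splitDataset(samples, 0.2, seed = 3)
  expect_length(sp@test, 122L)
  expect_length(sp@train, 490L)
  ids <- function(l) sort(unlist(l))
  expect_equal(sort(c(ids(sp@train), ids(sp@test))), 1:612)
  expect_length(intersect(ids(sp@train), ids(sp@test)), 0L)
  sp2 <- splitDataset(samples, 0.2, seed = 3)
  expect_identical(ids(sp2@test), ids(sp@test))
  sp3 <- splitDataset(samples, 0.2, seed = 4)
  expect_false(identical(ids(sp3@test), ids(sp@test)))
  expect_error(splitDataset(samples[1], 0.2, 1), "at least 2")
})

test_that("test membership is uniform across seeds", {
  n <- 10L
  hits <- numeric(n)
  for (seed in 1:200) {
    sp <- splitDataset(as.list(1:n), 0.2, seed)
    hits[unlist(sp@test)] <- hits[unlist(sp@test)] + 1
  }
  freq <- hits / 200
  se <- sqrt(0.2 * 0.8 / 200)
  expect_true(all(abs(freq - 0.2) < 5 * se))
})

test_that("empty-mask filtering keeps order and drops only empties", {
  mk <- function(id, fg) segmentationSample(matrix(0, 2, 2),
                                            matrix(c(fg, 0, 0, 0), 2), id)
  samples <- list(mk("a", 1), mk("b", 0), mk("c", 1), mk("d", 0), mk("e", 0))
  kept <- filterEmptyMasks(samples)
  expect_equal(vapply(kept, sampleId, character(1)), c("a", "c"))
  expect_length(filterEmptyMasks(samples[c(2, 4)]), 0L)
  expect_identical(filterEmptyMasks(samples[c(1, 3)]), samples[c(1, 3)])
})

test_that("padding to a multiple of 32 is symmetric and exactly invertible", {
  p0 <- padToMultiple(matrix(1, 320, 320))
  expect_equal(dim(p0$image), c(320L, 320L))
  expect_equal(unlist(p0$spec[c("left", "right", "top", "bottom")]),
               c(left = 0, right = 0, top = 0, bottom = 0))
  p <- padToMultiple(matrix(1, 320, 472))
  expect_equal(dim(p$image), c(320L, 480L))
  expect_equal(p$spec$left, 4L)
  expect_equal(p$spec$right, 4L)
  # odd remainder: the extra pixel goes bottom/right
  p33 <- padToMultiple(matrix(1, 33, 32))
  expect_equal(c(p33$spec$top, p33$spec$bottom), c(15L, 16L))
  set.seed(43)
  x <- matrix(rnorm(300 * 451), 300, 451)
  pr <- padToMultiple(x)
  expect_identical(cropBack(pr$image, pr$spec), x)
})

test_that("manifests round-trip through the generated-dataset dialect", {
  d <- withr::local_tempdir()
  generateDataset(synthConfig(n_samples = 3, seed = 5), d)
  samples <- readManifest(file.path(d, "manifest.tsv"))
  expect_length(samples, 3L)
  expect_true(all(vapply(samples, function(s) sum(sampleMask(s)) > 0, logical(1))))
  expect_equal(vapply(samples, sampleId, character(1)),
               sprintf("synth_%03d", 1:3))
  # masks written by writeMask load back unchanged
  f <- file.path(d, "roundtrip.png")
  m <- random_mask(8, 8)
  writeMask(m, f)
  make_png(matrix(1, 8, 8), file.path(d, "i.png"))
  s <- loadSample(file.path(d, "i.png"), f)
  expect_equal(sampleMask(s), m)
})
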