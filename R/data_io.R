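# Image/mask loading, grayscale conversion, per-image standardization,
# resizing, empty-mask filtering, the seeded 80/20 split, and the
# pad-to-multiple-of-32 round trip required by the five stride-2
# encoder levels. File decoding goes through EBImage (PNG/TIFF/BMP/JPEG);
# EBImage stores images (x, y) = (width, height), so arrays are
# transposed at the boundary into the package's (row = height) layout.

read_image_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    if (nch >= 3L) {
      # luminance conversion on the 8-bit scale
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  t(round(a * 255))
}

#' Load one image/mask pair
#'
#' Reads both files (PNG/TIFF/BMP/JPEG), converts RGB images to grayscale
#' by luminance (0.299 R + 0.587 G + 0.114 B on the 8-bit scale), and
#' binarizes 8-bit masks at value > 127.
#'
#' @param image_path,mask_path file paths.
#' @param id sample identifier (default: the image file name).
#' @param spacing optional pixel spacing in mm/px.
#' @return A [SegmentationSample-class]; the image is on the 0..255 scale.
#' @export
loadSample <- function(image_path, mask_path, id = basename(image_path),
                       spacing = NULL) {
  img <- read_image_gray(image_path)
  msk <- read_image_gray(mask_path)
  if (!all(dim(img) == dim(msk)))
    stop("image/mask shape mismatch for ", id, ": ",
         paste(dim(img), collapse = "x"), " vs ", paste(dim(msk), collapse = "x"))
  segmentationSample(img, (msk > 127) * 1, id, spacing)
}

#' Per-image z-score standardization
#'
#' Subtracts the image mean and divides by the population standard
#' deviation, so the output has mean 0 and population SD 1. A constant
#' image maps to all zeros (the SD is guarded with 1e-8).
#'
#' @param image numeric matrix or array.
#' @return list with `image` (standardized) and `params`, a list holding
#'   the `mean` and `s` that were removed.
#' @export
#' @examples
#' standardizeImage(c(1, 2, 3))$image   # -1.2247, 0, 1.2247
standardizeImage <- function(image) {
  if (length(image) == 0) stop("image is empty")
  mu <- mean(image)
  s <- sqrt(mean((image - mu)^2))
  out <- if (s > 0) (image - mu) / (s + 1e-8) else image * 0
  list(image = out, params = list(mean = mu, s = s))
}

resize_matrix <- function(m, width, height, filter) {
  # EBImage layout is (x = width, y = height)
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)),
                                       w = width, h = height,
                                       filter = filter)))
}

#' Resize an image/mask pair
#'
#' The image is bilinearly resampled; the mask uses nearest-neighbor so
#' it stays binary. The default target is the published 472 x 320
#' (width x height) working resolution for ultrasound/MRI frames.
#'
#' @param sample a [SegmentationSample-class].
#' @param width,height target size in pixels (width x height).
#' @return The resized [SegmentationSample-class].
#' @export
resizePair <- function(sample, width = 472L, height = 320L) {
  if (width < 1 || height < 1) stop("target dims must be >= 1")
  if (ncol(sample@image) == width && nrow(sample@image) == height)
    return(sample)
  img <- resize_matrix(sample@image, width, height, "bilinear")
  msk <- resize_matrix(sample@mask, width, height, "none")
  segmentationSample(img, (msk > 0.5) * 1, sample@id, sample@spacing)
}

#' Seeded random train/test split
#'
#' Uniformly shuffles the samples with the given seed and holds out
#' `round(n * test_fraction)` of them for testing.
#'
#' @param samples list of [SegmentationSample-class].
#' @param test_fraction proportion in (0, 1); default 0.2.
#' @param seed integer.
#' @return A [DatasetSplit-class].
#' @export
splitDataset <- function(samples, test_fraction = 0.2, seed = 1L) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- round(n * test_fraction)
  ord <- with_seed_(seed, sample.int(n))
  new("DatasetSplit",
      train = samples[ord[seq.int(n_test + 1L, n)]],
      test = samples[ord[seq_len(n_test)]],
      seed = as.integer(seed), test_fraction = test_fraction)
}

#' Drop samples whose mask is empty
#'
#' Retains (in order) only samples with at least one foreground pixel.
#'
#' @param samples list of [SegmentationSample-class].
#' @return the filtered list.
#' @export
filterEmptyMasks <- function(samples) {
  Filter(function(s) sum(s@mask) > 0, samples)
}

#' Zero-pad an image up to the next multiple of m
#'
#' Symmetric padding with the extra pixel going to the bottom/right on
#' odd remainders. Needed because the five stride-2 encoder levels
#' require spatial dims divisible by 32 (the published width 472 is not).
#' [cropBack()] exactly inverts the padding.
#'
#' @param image numeric matrix.
#' @param m divisibility target (default 32).
#' @return list with `image` (padded) and `spec`, a list of per-side pad
#'   widths and the original dims.
#' @export
#' @examples
#' p <- padToMultiple(matrix(0, 320, 472))
#' dim(p$image)          # 320 480
#' p$spec[c("left", "right")]
padToMultiple <- function(image, m = 32L) {
  if (m < 1L) stop("m must be >= 1")
  d <- dim(image)
  tot_h <- (m - d[1] %% m) %% m
  tot_w <- (m - d[2] %% m) %% m
  spec <- list(top = tot_h %/% 2L, bottom = tot_h - tot_h %/% 2L,
               left = tot_w %/% 2L, right = tot_w - tot_w %/% 2L,
               height = d[1], width = d[2])
  out <- matrix(0, d[1] + tot_h, d[2] + tot_w)
  out[spec$top + seq_len(d[1]), spec$left + seq_len(d[2])] <- image
  list(image = out, spec = spec)
}

#' @rdname padToMultiple
#' @param spec the pad spec returned by `padToMultiple`.
#' @export
cropBack <- function(image, spec) {
  image[spec$top + seq_len(spec$height), spec$left + seq_len(spec$width),
        drop = FALSE]
}

#' Read a dataset manifest
#'
#' The manifest is a TSV with one row per sample and columns `id`,
#' `image`, `mask`, and optionally `spacing_mm_per_px`. Paths are
#' resolved relative to the manifest's directory unless absolute.
#'
#' @param path manifest file path.
#' @return list of [SegmentationSample-class].
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "image", "mask")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(tab)), function(i) {
    sp <- if ("spacing_mm_per_px" %in% names(tab) &&
              !is.na(tab$spacing_mm_per_px[i])) tab$spacing_mm_per_px[i] else NULL
    loadSample(resolve(tab$image[i]), resolve(tab$mask[i]),
               id = tab$id[i], spacing = sp)
  })
}

#' Write a predicted mask as an 8-bit PNG (0/255)
#'
#' @param mask binary matrix.
#' @param path output path (extension selects the format; use .png).
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  check_binary(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path)
  invisible(path)
}
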