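# Segmentation losses and evaluation metrics: soft Dice / minus-Dice
# loss on probability maps, hard Dice and Jaccard on binary masks, and
# the symmetric Hausdorff distance on extracted contours.

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("inputs must have the same shape (",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"), ")")
}

check_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) stop(what, " entries must be 0 or 1")
}

#' Soft Dice coefficient
#'
#' `(2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`,
#' the continuous relaxation of the Dice similarity coefficient used to
#' train the network. Equals the hard coefficient (up to `eps`) when
#' `pred` is binary.
#'
#' @param pred probability map, entries in \[0, 1\].
#' @param target binary mask of the same shape.
#' @param eps smoothing constant keeping the empty-empty case finite.
#' @return value in \[0, 1\].
#' @export
#' @examples
#' softDice(matrix(c(0.5, 0.5, 0.5, 0.5), 2), matrix(c(1, 1, 0, 0), 2)) # 0.5
softDice <- function(pred, target, eps = 1e-6) {
  check_same_shape(pred, target)
  if (eps <= 0) stop("eps must be > 0")
  (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

#' Minus-Dice training loss
#'
#' The negative of [softDice()]; values lie in \[-1, 0\] with -1 at a
#' perfect prediction, matching the convention under which training
#' curves show negative loss values.
#'
#' @inheritParams softDice
#' @return value in \[-1, 0\].
#' @export
diceLoss <- function(pred, target, eps = 1e-6) -softDice(pred, target, eps)

#' Hard Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` by pixel counting. Two empty masks score
#' 1.0 by convention; one empty mask scores 0.
#'
#' @param a,b binary masks of the same shape.
#' @return value in \[0, 1\].
#' @export
hardDice <- function(a, b) {
  check_same_shape(a, b)
  check_binary(a, "a"); check_binary(b, "b")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Jaccard similarity coefficient
#'
#' `|A n B| / |A u B|`. Related to the Dice coefficient by
#' `J = D / (2 - D)`. Two empty masks score 1.0.
#'
#' @inheritParams hardDice
#' @return value in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_same_shape(a, b)
  check_binary(a, "a"); check_binary(b, "b")
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Extract the boundary pixels of a binary mask
#'
#' A foreground pixel belongs to the contour when at least one of its
#' 4-neighbors is background, or when it lies on the image border. An
#' empty mask yields a zero-row result with attribute `empty = TRUE`,
#' which signals an undefined Hausdorff distance downstream.
#'
#' @param mask binary matrix.
#' @return two-column integer matrix of (row, col) contour coordinates.
#' @export
extractContour <- function(mask) {
  check_binary(mask)
  d <- dim(mask)
  if (sum(mask) == 0) {
    out <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("row", "col")))
    attr(out, "empty") <- TRUE
    return(out)
  }
  padded <- matrix(0, d[1] + 2L, d[2] + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  core <- function(dr, dc) padded[2:(d[1] + 1L) + dr, 2:(d[2] + 1L) + dc]
  nb_bg <- (core(-1L, 0L) == 0) | (core(1L, 0L) == 0) |
           (core(0L, -1L) == 0) | (core(0L, 1L) == 0)
  on_contour <- mask == 1 & nb_bg
  idx <- which(on_contour, arr.ind = TRUE)
  out <- matrix(as.integer(idx), ncol = 2L,
                dimnames = list(NULL, c("row", "col")))
  attr(out, "empty") <- FALSE
  out
}

#' Symmetric Hausdorff distance between two contours
#'
#' `max(max_a min_b d(a, b), max_b min_a d(a, b))` with Euclidean
#' distance, i.e. the larger of the two directed maximum
#' point-to-nearest-point distances. Reported in pixels, or in mm when a
#' pixel `spacing` is supplied.
#'
#' @param a,b contour point matrices from [extractContour()] (or any
#'   two-column (row, col) matrices).
#' @param spacing optional pixel spacing in mm/px.
#' @return distance >= 0, or an error if either contour is empty.
#' @export
#' @examples
#' hausdorffDistance(rbind(c(0, 0)), rbind(c(3, 4)))   # 5
hausdorffDistance <- function(a, b, spacing = NULL) {
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("Hausdorff distance is undefined for an empty contour")
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  hd <- sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
  if (!is.null(spacing)) hd <- hd * spacing
  hd
}

#' Threshold a probability map into a binary mask
#'
#' `entry >= threshold` maps to 1 (a value of exactly 0.5 at the default
#' threshold is foreground), else 0. Idempotent on binary input.
#'
#' @param prob probability map.
#' @param threshold in (0, 1); default 0.5.
#' @return binary array shaped like `prob`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  out <- (prob >= threshold) * 1
  out
}

#' Build a per-sample / aggregate metric report
#'
#' @param ids character vector of sample identifiers.
#' @param dsc,jsc numeric metric vectors.
#' @param hd numeric Hausdorff distances; NA where undefined (those are
#'   excluded from the summary and counted).
#' @return A [MetricReport-class].
#' @export
metricReport <- function(ids, dsc, jsc, hd) {
  per <- data.frame(id = as.character(ids), dsc = dsc, jsc = jsc, hd = hd,
                    stringsAsFactors = FALSE)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  hd_ok <- hd[!is.na(hd)]
  summ <- data.frame(
    metric = c("dsc", "jsc", "hd"),
    mean = c(mean(dsc), mean(jsc), if (length(hd_ok)) mean(hd_ok) else NA_real_),
    sd = c(sd0(dsc), sd0(jsc), if (length(hd_ok)) sd0(hd_ok) else NA_real_))
  new("MetricReport", per_sample = per, summary = summ,
      n = length(ids), hd_undefined = sum(is.na(hd)))
}

#' Write a metric report as CSV
#'
#' Columns id, dsc, jsc, hd; two footer rows hold the mean and standard
#' deviation of each metric.
#'
#' @param report a [MetricReport-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  per <- report@per_sample
  s <- report@summary
  footer <- data.frame(id = c("mean", "sd"),
                       dsc = c(s$mean[1], s$sd[1]),
                       jsc = c(s$mean[2], s$sd[2]),
                       hd = c(s$mean[3], s$sd[3]))
  utils::write.csv(rbind(per, footer), path, row.names = FALSE)
  invisible(path)
}
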