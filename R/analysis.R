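# Clinical agreement analytics: structure length by maximum Feret
# diameter of the largest connected component, Bland-Altman limits of
# agreement between automatic and manual measurements, Pearson
# correlation, and Tukey box-whisker summaries.

# 8-connected component labels of a binary mask (igraph connected
# components over the pixel adjacency graph).
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask == 1)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0L) return(lab)
  vid <- matrix(0L, H, W)
  vid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  edges <- NULL
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nr <- r + off[1]; nc <- c + off[2]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nidx <- nr[ok] + (nc[ok] - 1L) * H
    hit <- vid[nidx] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(vid[idx[ok]][hit], vid[nidx][hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Structure length as the maximum Feret diameter
#'
#' Takes the largest 8-connected foreground component of the mask and
#' returns the maximum pairwise Euclidean distance between its contour
#' points -- the caliper "crown to rump" extent -- in pixels, or in mm
#' when a pixel spacing is supplied. A single-pixel component has length
#' 0.
#'
#' @param mask binary matrix.
#' @param spacing optional pixel spacing in mm/px.
#' @return length >= 0; empty masks raise an error.
#' @export
#' @examples
#' m <- matrix(0, 5, 7); m[3, 2:6] <- 1
#' measureLength(m)   # 4
measureLength <- function(mask, spacing = NULL) {
  check_binary(mask)
  if (sum(mask) == 0) stop("length is undefined for an empty mask")
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  comp <- (lab == which.max(sizes)) * 1
  pts <- extractContour(comp)
  if (nrow(pts) == 1L) return(0)
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  len <- sqrt(max(d2))
  if (!is.null(spacing)) len <- len * spacing
  len
}

#' Bland-Altman limits of agreement
#'
#' For paired automatic/manual measurements, computes the differences
#' `d = auto - manual`, their mean (the bias), the sample standard
#' deviation (n - 1 denominator), and the normal-theory 95% limits of
#' agreement `bias +/- 1.96 sd`.
#'
#' @param auto,manual numeric vectors of equal length (n >= 2).
#' @return A [BlandAltmanResult-class].
#' @export
#' @examples
#' blandAltman(c(2, 1), c(1, 2))   # bias 0, limits +/- 2.77186
blandAltman <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("auto and manual lengths differ")
  n <- length(auto)
  if (n < 2L) stop("need at least 2 measurement pairs")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  new("BlandAltmanResult", bias = bias, sd = s,
      loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
      n = as.integer(n))
}

#' Pearson product-moment correlation of paired measurements
#'
#' @inheritParams blandAltman
#' @return correlation in \[-1, 1\]; an error if either variable is
#'   constant.
#' @export
pearsonCorrelation <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("auto and manual lengths differ")
  if (length(auto) < 2L) stop("need at least 2 measurement pairs")
  if (stats::sd(auto) == 0 || stats::sd(manual) == 0)
    stop("correlation is undefined for a constant variable")
  stats::cor(auto, manual)
}

#' Tukey box-whisker summary
#'
#' Quartiles by linear interpolation between order statistics
#' (`quantile` type 7), fences at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`,
#' whiskers at the most extreme data inside the fences, and all values
#' outside the whisker interval listed as outliers.
#'
#' @param values numeric vector (n >= 1).
#' @return A [WhiskerSummary-class].
#' @export
#' @examples
#' whiskerSummary(c(0, 0, 0, 0, 100))   # 100 flagged as outlier
whiskerSummary <- function(values) {
  if (length(values) < 1L) stop("need at least 1 value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  wl <- min(inside); wh <- max(inside)
  new("WhiskerSummary", median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = wl, whisker_high = wh,
      outliers = values[values < wl | values > wh])
}
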