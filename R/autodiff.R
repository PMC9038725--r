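# Reverse-mode autodiff tape over (H, W, C) feature arrays, batch size 1.
# Nodes are environments appended to the tape in creation order; backward
# walks the tape in reverse, accumulating gradients at shared parents so
# arbitrary DAGs (skip connections, cross-network reuse) are handled.
#
# Internal layout: feature maps are 3-D (H, W, C) double arrays; the
# public FeatureMap contract (1, H, W, C) is converted at the API edge.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

tp_leaf <- function(tape, value) tp_node(tape, value)

tape_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  invisible(NULL)
}

# "same" padding for stride-s conv: out = ceil(in / s); extra pad goes to
# the bottom/right side on odd totals.
same_pad <- function(n, k, s) {
  o <- ceiling(n / s)
  tot <- max((o - 1L) * s + k - n, 0L)
  c(out = o, before = tot %/% 2L, total = tot)
}

as_hwc <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  storage.mode(x) <- "double"
  x
}

# -- convolution ------------------------------------------------------------

# x: (H, W, Cin); W: (kh, kw, Cin, Cout); b: length Cout
tp_conv2d <- function(tape, x, w, b, stride) {
  xv <- x$value; wv <- w$value; bv <- b$value
  dk <- dim(wv)
  kh <- dk[1]; kw <- dk[2]; cin <- dk[3]; cout <- dk[4]
  dx <- dim(xv)
  if (dx[3] != cin) stop("conv2d: input has ", dx[3], " channels, kernel expects ", cin)
  ph <- same_pad(dx[1], kh, stride); pw <- same_pad(dx[2], kw, stride)
  oh <- ph[["out"]]; ow <- pw[["out"]]
  if (oh < 1 || ow < 1) stop("conv2d: non-positive output dims")
  cols <- cpp_im2col(xv, kh, kw, stride, stride,
                     ph[["before"]], pw[["before"]], oh, ow)
  out <- crossprod(cols, matrix(wv, ncol = cout))
  out <- out + rep(bv, each = oh * ow)
  val <- array(out, c(oh, ow, cout))
  tp_node(tape, val, list(x, w, b), function(g) {
    gm <- matrix(g, oh * ow, cout)
    dw <- array(cols %*% gm, dk)
    db <- colSums(gm)
    dcols <- matrix(wv, ncol = cout) %*% t(gm)
    dxv <- cpp_col2im(dcols, dx[1], dx[2], cin, kh, kw, stride, stride,
                      ph[["before"]], pw[["before"]], oh, ow)
    list(dxv, dw, db)
  })
}

# Transposed convolution, stride 2, output exactly doubles each spatial
# axis (the adjoint of a same-padded stride-2 convolution).
# x: (H, W, Cin); K: (kh, kw, Cout, Cin); b: length Cout
tp_convt2d <- function(tape, x, k, b) {
  xv <- x$value; kv <- k$value; bv <- b$value
  dk <- dim(kv)
  kh <- dk[1]; kw <- dk[2]; cout <- dk[3]; cin <- dk[4]
  dx <- dim(xv)
  if (dx[3] != cin) stop("convt2d: input has ", dx[3], " channels, kernel expects ", cin)
  H <- dx[1]; W <- dx[2]; Hb <- 2L * H; Wb <- 2L * W
  ph <- same_pad(Hb, kh, 2L); pw <- same_pad(Wb, kw, 2L)
  stopifnot(ph[["out"]] == H, pw[["out"]] == W)
  kmat <- matrix(kv, kh * kw * cout, cin)
  xmat <- matrix(xv, H * W, cin)
  cols <- kmat %*% t(xmat)
  y <- cpp_col2im(cols, Hb, Wb, cout, kh, kw, 2L, 2L,
                  ph[["before"]], pw[["before"]], H, W)
  y <- y + rep(bv, each = Hb * Wb)
  tp_node(tape, y, list(x, k, b), function(g) {
    gcols <- cpp_im2col(g, kh, kw, 2L, 2L,
                        ph[["before"]], pw[["before"]], H, W)
    dxv <- array(crossprod(gcols, kmat), c(H, W, cin))
    dkv <- array(gcols %*% xmat, dk)
    db <- colSums(matrix(g, Hb * Wb, cout))
    list(dxv, dkv, db)
  })
}

# -- batch normalization ----------------------------------------------------

# Per-channel normalization over the spatial axes (batch size 1).
# state[[key]] holds running mean/var; training mode uses batch statistics
# and updates the running ones (momentum 0.99, eps 1e-3).
tp_batchnorm <- function(tape, x, gamma, beta, state, key, training,
                         momentum = 0.99, eps = 1e-3) {
  xv <- x$value
  d <- dim(xv)
  m <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, m, C)
  gv <- gamma$value; bv <- beta$value
  rs <- state[[key]]
  if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    va <- pmax(va, 0)
    state[[key]] <- list(mean = momentum * rs$mean + (1 - momentum) * mu,
                         var  = momentum * rs$var  + (1 - momentum) * va)
  } else {
    mu <- rs$mean
    va <- rs$var
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = m)) * rep(inv_std, each = m)
  ym <- xhat * rep(gv, each = m) + rep(bv, each = m)
  tp_node(tape, array(ym, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, m, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- gm * rep(gv, each = m)
    if (training) {
      dxm <- rep(inv_std / m, each = m) *
        (m * dxhat - rep(colSums(dxhat), each = m) -
           xhat * rep(colSums(dxhat * xhat), each = m))
    } else {
      dxm <- dxhat * rep(inv_std, each = m)
    }
    list(array(dxm, d), dgamma, dbeta)
  })
}

# -- pointwise nonlinearities ----------------------------------------------

tp_leaky_relu <- function(tape, x, slope) {
  xv <- x$value
  val <- ifelse(xv > 0, xv, slope * xv)
  tp_node(tape, val, list(x), function(g) {
    list(g * ifelse(xv > 0, 1, slope))
  })
}

tp_relu <- function(tape, x) {
  xv <- x$value
  val <- pmax(xv, 0)
  tp_node(tape, val, list(x), function(g) list(g * (xv > 0)))
}

tp_sigmoid <- function(tape, x) {
  val <- 1 / (1 + exp(-x$value))
  tp_node(tape, val, list(x), function(g) list(g * val * (1 - val)))
}

# Inverted dropout: identity in inference mode.
tp_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) {
    return(tp_node(tape, x$value, list(x), function(g) list(g)))
  }
  keep <- 1 - rate
  mask <- array((stats::runif(length(x$value)) < keep) / keep, dim(x$value))
  tp_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

# -- structural ops ---------------------------------------------------------

tp_concat <- function(tape, xs) {
  vals <- lapply(xs, function(n) n$value)
  dims <- lapply(vals, dim)
  h <- dims[[1]][1]; w <- dims[[1]][2]
  for (d in dims) {
    if (d[1] != h || d[2] != w)
      stop("concat: spatial dims differ (", d[1], "x", d[2], " vs ", h, "x", w, ")")
  }
  chans <- vapply(dims, `[`, integer(1), 3L)
  val <- array(unlist(vals, use.names = FALSE), c(h, w, sum(chans)))
  ends <- cumsum(chans)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_node(tape, val, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      array(g[, , starts[i]:ends[i], drop = FALSE], dims[[i]])
    })
  })
}

# y = x * alpha with alpha (H, W, 1) broadcast over x's channels
tp_mul_alpha <- function(tape, x, alpha) {
  xv <- x$value; av <- alpha$value
  dx <- dim(xv)
  if (!all(dim(av)[1:2] == dx[1:2]) || dim(av)[3] != 1L)
    stop("mul_alpha: alpha must be single-channel at x's resolution")
  am <- as.vector(av)
  val <- array(as.vector(xv) * am, dx)
  tp_node(tape, val, list(x, alpha), function(g) {
    da <- array(rowSums(matrix(g * xv, dx[1] * dx[2], dx[3])), c(dx[1], dx[2], 1L))
    list(array(as.vector(g) * am, dx), da)
  })
}

tp_mul <- function(tape, x, y) {
  xv <- x$value; yv <- y$value
  stopifnot(all(dim(xv) == dim(yv)))
  tp_node(tape, xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

tp_add <- function(tape, x, y) {
  stopifnot(all(dim(x$value) == dim(y$value)))
  tp_node(tape, x$value + y$value, list(x, y), function(g) list(g, g))
}

# -- x2 spatial upsampling --------------------------------------------------

# Interpolation matrix (2n x n) with half-pixel centers; "nearest" or
# "bilinear". Linear in the input, so the backward pass is the transpose.
up2_matrix <- function(n, method) {
  m <- 2L * n
  A <- matrix(0, m, n)
  for (io in seq_len(m) - 1L) {
    if (method == "nearest") {
      A[io + 1L, io %/% 2L + 1L] <- 1
    } else {
      src <- io / 2 - 0.25
      i0 <- floor(src)
      wts <- src - i0
      i0c <- min(max(i0, 0), n - 1)
      i1c <- min(max(i0 + 1, 0), n - 1)
      A[io + 1L, i0c + 1L] <- A[io + 1L, i0c + 1L] + (1 - wts)
      A[io + 1L, i1c + 1L] <- A[io + 1L, i1c + 1L] + wts
    }
  }
  A
}

tp_upsample2x <- function(tape, x, method = "bilinear") {
  xv <- x$value
  d <- dim(xv)
  Ah <- up2_matrix(d[1], method)
  Aw <- up2_matrix(d[2], method)
  val <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  for (c in seq_len(d[3])) val[, , c] <- Ah %*% xv[, , c] %*% t(Aw)
  tp_node(tape, val, list(x), function(g) {
    dxv <- array(0, d)
    for (c in seq_len(d[3])) dxv[, , c] <- crossprod(Ah, g[, , c]) %*% Aw
    list(dxv)
  })
}

# -- losses -----------------------------------------------------------------

# Minus soft Dice; pred is a node, target a plain array of the same shape.
tp_dice_loss <- function(tape, pred, target, eps = 1e-6) {
  pv <- pred$value
  stopifnot(all(dim(pv) == dim(target)))
  num <- 2 * sum(pv * target) + eps
  den <- sum(pv) + sum(target) + eps
  tp_node(tape, -num / den, list(pred), function(g) {
    list(g * (-(2 * target * den - num) / den^2))
  })
}

# a + w * b for scalar nodes
tp_add_scaled <- function(tape, a, b, w) {
  tp_node(tape, a$value + w * b$value, list(a, b),
          function(g) list(g, w * g))
}
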