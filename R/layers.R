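# Layer composites. Each layer exists at two levels:
#  * a tape-level builder (op_*) used inside the model graphs, taking and
#    returning autodiff nodes over (H, W, C) arrays;
#  * an exported array-level function taking the public (1, H, W, C)
#    FeatureMap layout, for direct inspection and testing.

# -- public FeatureMap layout helpers --------------------------------------

fm_in <- function(x, what = "input") {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x), 1L))
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop(what, " must be a 4-axis (batch, height, width, channels) array")
  if (d[1] != 1L) stop("only batch size 1 is supported")
  if (any(d < 1L)) stop(what, " has a non-positive axis")
  if (!all(is.finite(x))) stop(what, " must be finite")
  array(as.double(x), d[2:4])
}

fm_out <- function(x) array(x, c(1L, dim(x)))

# -- parameter initialization ----------------------------------------------

# Conv weights: zero-mean normal, sd hp@init_std; biases zero; batch-norm
# scale 1 / shift 0 (running stats start at mean 0, var 1).
init_conv_w <- function(kh, kw, cin, cout, std) {
  array(stats::rnorm(kh * kw * cin * cout, 0, std), c(kh, kw, cin, cout))
}

init_encoder_params <- function(cin, f, hp) {
  k <- hp@kernel_size
  list(W = init_conv_w(k[1], k[2], cin, f, hp@init_std), b = numeric(f),
       gamma = rep(1, f), beta = numeric(f))
}

init_decoder_params <- function(cin, f, hp) {
  k <- hp@kernel_size
  # transposed-conv kernel layout: (kh, kw, out_channels, in_channels)
  list(K = array(stats::rnorm(k[1] * k[2] * f * cin, 0, hp@init_std),
                 c(k[1], k[2], f, cin)),
       b = numeric(f), gamma = rep(1, f), beta = numeric(f))
}

init_residual_params <- function(f, hp) {
  k <- hp@kernel_size
  list(W1 = init_conv_w(k[1], k[2], f, f, hp@init_std), b1 = numeric(f),
       gamma1 = rep(1, f), beta1 = numeric(f),
       W2 = init_conv_w(k[1], k[2], f, f, hp@init_std), b2 = numeric(f),
       gamma2 = rep(1, f), beta2 = numeric(f))
}

init_attention_params <- function(f_l, f_g, f_int, hp) {
  list(Wx = init_conv_w(1L, 1L, f_l, f_int, hp@init_std),
       Wg = init_conv_w(1L, 1L, f_g, f_int, hp@init_std),
       b_g = numeric(f_int),
       psi = init_conv_w(1L, 1L, f_int, 1L, hp@init_std),
       b_psi = numeric(1))
}

init_head_params <- function(cin, cout, hp) {
  k <- hp@kernel_size
  list(K = array(stats::rnorm(k[1] * k[2] * cout * cin, 0, hp@init_std),
                 c(k[1], k[2], cout, cin)),
       b = numeric(cout))
}

wrap_params <- function(tape, plist) lapply(plist, function(v) tp_leaf(tape, v))

# -- tape-level composites --------------------------------------------------

# conv (5x5, stride 2, same) -> batch-norm -> leaky rectifier
op_encoder_block <- function(tape, x, pn, hp, state, key, training) {
  h <- tp_conv2d(tape, x, pn$W, pn$b, hp@stride[1])
  h <- tp_batchnorm(tape, h, pn$gamma, pn$beta, state, key, training)
  tp_leaky_relu(tape, h, hp@leaky_slope)
}

# transposed conv (x2) -> batch-norm -> dropout -> concat skips -> rectifier
op_decoder_block <- function(tape, x, skips, pn, hp, state, key, training) {
  for (s in skips) {
    if (!all(dim(s$value)[1:2] == 2L * dim(x$value)[1:2]))
      stop("decoder skip spatial dims must be exactly twice the input's")
  }
  h <- tp_convt2d(tape, x, pn$K, pn$b)
  h <- tp_batchnorm(tape, h, pn$gamma, pn$beta, state, key, training)
  h <- tp_dropout(tape, h, hp@dropout_rate, training)
  h <- tp_concat(tape, c(skips, list(h)))
  tp_relu(tape, h)
}

# H_k = F(H_{k-1}) + H_{k-1}; F = bn2 . conv2 . bn1 . conv1, stride 1,
# no nonlinearity after the second conv
op_residual_block <- function(tape, h, pn, hp, state, key, training) {
  f <- tp_conv2d(tape, h, pn$W1, pn$b1, 1L)
  f <- tp_batchnorm(tape, f, pn$gamma1, pn$beta1, state, paste0(key, ".1"), training)
  f <- tp_conv2d(tape, f, pn$W2, pn$b2, 1L)
  f <- tp_batchnorm(tape, f, pn$gamma2, pn$beta2, state, paste0(key, ".2"), training)
  tp_add(tape, f, h)
}

# Additive attention: alpha = sigmoid(psi(relu(Wx x + Wg up2(g) + b_g)) + b_psi)
op_attention_gate <- function(tape, x, g, pn, upsample_mode) {
  dx <- dim(x$value); dg <- dim(g$value)
  if (!all(dx[1:2] == 2L * dg[1:2]))
    stop("attention gate: g must be at half of x's resolution")
  gu <- tp_upsample2x(tape, g, upsample_mode)
  hx <- tp_conv2d(tape, x, pn$Wx, tp_leaf(tape, numeric(dim(pn$Wx$value)[4])), 1L)
  hg <- tp_conv2d(tape, gu, pn$Wg, pn$b_g, 1L)
  h <- tp_relu(tape, tp_add(tape, hx, hg))
  q <- tp_conv2d(tape, h, pn$psi, pn$b_psi, 1L)
  alpha <- tp_sigmoid(tape, q)
  list(gated = tp_mul_alpha(tape, x, alpha), alpha = alpha)
}

# transposed conv (x2) to output_channels -> sigmoid
op_output_head <- function(tape, x, pn) {
  tp_sigmoid(tape, tp_convt2d(tape, x, pn$K, pn$b))
}

# -- exported array-level layer functions -----------------------------------

#' Encoder block: strided convolution, batch-norm, leaky rectifier
#'
#' One downsampling step of the encoder path: a same-padded 5x5
#' convolution swept with stride 2, batch normalization, and a leaky
#' rectifier with negative slope 0.2. Spatial dims halve
#' (ceil(input/2)); channels become `filters`.
#'
#' @param x input feature map, a (1, height, width, channels) array.
#' @param filters output channel count.
#' @param hp a [LayerHyperParams-class].
#' @param params optional named list (W, b, gamma, beta); freshly
#'   initialized (normal sd `hp@init_std`, zero biases) when NULL.
#' @param training logical; training-mode batch statistics if TRUE.
#' @return A (1, ceil(h/2), ceil(w/2), filters) array.
#' @export
#' @examples
#' x <- array(rnorm(64 * 64), c(1, 64, 64, 1))
#' dim(encoderBlock(x, 20))   # 1 32 32 20
encoderBlock <- function(x, filters, hp = layerHyperParams(), params = NULL,
                         training = FALSE) {
  xv <- fm_in(x)
  if (filters <= 0) stop("filters must be > 0")
  if (is.null(params)) params <- init_encoder_params(dim(xv)[3], filters, hp)
  tp <- new_tape()
  st <- new.env(parent = emptyenv())
  out <- op_encoder_block(tp, tp_leaf(tp, xv), wrap_params(tp, params), hp,
                          st, "bn", training)
  fm_out(out$value)
}

#' Decoder block: transposed convolution, batch-norm, dropout, skip concat
#'
#' One upsampling step of the decoder path: a same-padded 5x5 transposed
#' convolution with stride 2 (spatial dims double), batch normalization,
#' dropout (30%, training mode only), channel concatenation of the skip
#' feature maps, then a rectifier. Output channels =
#' `filters + sum of skip channels`; all entries are >= 0.
#'
#' @param x input feature map (1, h, w, c) array.
#' @param skips list of skip feature maps, each (1, 2h, 2w, c_k).
#' @param filters transposed-convolution filter count.
#' @inheritParams encoderBlock
#' @return A (1, 2h, 2w, filters + sum(skip channels)) array.
#' @export
decoderBlock <- function(x, skips, filters, hp = layerHyperParams(),
                         params = NULL, training = FALSE) {
  xv <- fm_in(x)
  sk <- lapply(skips, fm_in, what = "skip")
  if (is.null(params)) params <- init_decoder_params(dim(xv)[3], filters, hp)
  tp <- new_tape()
  st <- new.env(parent = emptyenv())
  out <- op_decoder_block(tp, tp_leaf(tp, xv), lapply(sk, tp_leaf, tape = tp),
                          wrap_params(tp, params), hp, st, "bn", training)
  fm_out(out$value)
}

#' Residual block with post-conv batch normalization
#'
#' Computes `F(h) + h` where F is conv(5x5, stride 1) -> batch-norm ->
#' conv(5x5, stride 1) -> batch-norm, with no nonlinearity after the
#' second convolution. Shape is preserved; zeroing the branch weights
#' makes the block an exact identity in inference mode.
#'
#' @param h input feature map (1, height, width, filters).
#' @param filters channel count (input and output; default from `h`).
#' @inheritParams encoderBlock
#' @return An array shaped like `h`.
#' @export
residualBlock <- function(h, filters = NULL, hp = layerHyperParams(),
                          params = NULL, training = FALSE) {
  hv <- fm_in(h)
  if (is.null(filters)) filters <- dim(hv)[3]
  if (dim(hv)[3] != filters)
    stop("residual block: input has ", dim(hv)[3], " channels, expected ", filters)
  if (is.null(params)) params <- init_residual_params(filters, hp)
  tp <- new_tape()
  st <- new.env(parent = emptyenv())
  out <- op_residual_block(tp, tp_leaf(tp, hv), wrap_params(tp, params), hp,
                           st, "bn", training)
  fm_out(out$value)
}

#' A stack of residual blocks
#'
#' `n` sequential applications of [residualBlock()]; the bottleneck of
#' each network uses n = 4.
#'
#' @inheritParams residualBlock
#' @param n number of blocks (>= 1).
#' @param params optional list of `n` residual parameter lists.
#' @return An array shaped like `h`.
#' @export
residualStack <- function(h, n = 4L, filters = NULL, hp = layerHyperParams(),
                          params = NULL, training = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  hv <- fm_in(h)
  if (is.null(filters)) filters <- dim(hv)[3]
  if (is.null(params))
    params <- replicate(n, init_residual_params(filters, hp), simplify = FALSE)
  out <- h
  for (k in seq_len(n))
    out <- residualBlock(out, filters, hp, params[[k]], training)
  out
}

#' Additive attention gate
#'
#' Rescales an encoder skip feature map `x` by a learned per-pixel
#' coefficient computed against a coarser gating signal `g` (half of
#' `x`'s resolution): `g` is upsampled by 2, both inputs are mapped to an
#' intermediate channel space by 1x1 convolutions, summed with a bias and
#' rectified, reduced to one channel by the 1x1 convolution psi plus its
#' bias, and squashed by a sigmoid. The single-channel coefficient map
#' `alpha` (entries strictly in (0, 1)) multiplies `x` across channels.
#'
#' @param x skip feature map (1, h, w, f_l).
#' @param g gating feature map (1, h/2, w/2, f_g).
#' @param f_int intermediate channel count (default max(1, f_l / 2)).
#' @param params optional named list (Wx, Wg, b_g, psi, b_psi).
#' @param upsample_mode "bilinear" (default) or "nearest".
#' @param hp a [LayerHyperParams-class] (initialization SD).
#' @return list with `gated` (1, h, w, f_l) and `alpha` (1, h, w, 1).
#' @export
#' @examples
#' # zero psi forces alpha = sigmoid(0) = 0.5 and gated = x / 2
#' x <- array(rnorm(2 * 2 * 3), c(1, 2, 2, 3))
#' g <- array(rnorm(1 * 1 * 5), c(1, 1, 1, 5))
#' p <- list(Wx = array(0, c(1, 1, 3, 2)), Wg = array(0, c(1, 1, 5, 2)),
#'           b_g = numeric(2), psi = array(0, c(1, 1, 2, 1)), b_psi = 0)
#' out <- attentionGate(x, g, params = p)
#' stopifnot(all(out$alpha == 0.5), all(out$gated == x / 2))
attentionGate <- function(x, g, f_int = NULL, params = NULL,
                          upsample_mode = "bilinear",
                          hp = layerHyperParams()) {
  xv <- fm_in(x); gv <- fm_in(g, "gating signal")
  if (is.null(f_int)) f_int <- max(1L, dim(xv)[3] %/% 2L)
  if (is.null(params))
    params <- init_attention_params(dim(xv)[3], dim(gv)[3], f_int, hp)
  tp <- new_tape()
  out <- op_attention_gate(tp, tp_leaf(tp, xv), tp_leaf(tp, gv),
                           wrap_params(tp, params), upsample_mode)
  list(gated = fm_out(out$gated$value), alpha = fm_out(out$alpha$value))
}

#' Sigmoid output head
#'
#' The final layer of each network: a same-padded 5x5 transposed
#' convolution with stride 2 down to `channels` output maps, followed by
#' a sigmoid. Spatial dims double; entries are strictly in (0, 1).
#'
#' @param x last decoder block output (1, h, w, c).
#' @param channels output channel count (default 1).
#' @inheritParams encoderBlock
#' @param params optional named list (K, b).
#' @return A (1, 2h, 2w, channels) array with entries in (0, 1).
#' @export
outputHead <- function(x, channels = 1L, hp = layerHyperParams(),
                       params = NULL) {
  xv <- fm_in(x)
  if (is.null(params)) params <- init_head_params(dim(xv)[3], channels, hp)
  tp <- new_tape()
  out <- op_output_head(tp, tp_leaf(tp, xv), wrap_params(tp, params))
  fm_out(out$value)
}
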