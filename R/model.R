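# Network assembly and forward passes.
#
# Parameter naming inside a SingleNetModel's params environment:
#   enc{i}.{W,b,gamma,beta}           encoder blocks, i = 1..n_levels
#   res{k}.{W1,b1,gamma1,beta1,...}   residual blocks, k = 1..n_residual
#   ag{k}.{Wx,Wg,b_g,psi,b_psi}       attention gates, k = 1 deepest
#   dec{k}.{K,b,gamma,beta}           decoder blocks, k = 1 deepest
#   head.{K,b}                        sigmoid output head
# Batch-norm running statistics live in the state environment under the
# corresponding block key and are not trainable.

init_single_net_params <- function(cfg, in_channels = 1L, dual_skips = FALSE) {
  hp <- cfg@hyper
  ef <- cfg@encoder_filters
  df <- cfg@decoder_filters
  ne <- length(ef)
  penv <- new.env(parent = emptyenv())
  put <- function(prefix, plist) {
    for (nm in names(plist)) assign(paste0(prefix, ".", nm), plist[[nm]], penv)
  }
  cin <- in_channels
  for (i in seq_len(ne)) {
    put(paste0("enc", i), init_encoder_params(cin, ef[i], hp))
    cin <- ef[i]
  }
  if (cfg@residual_filters != ef[ne])
    stop("residual_filters must equal the deepest encoder filter count")
  for (k in seq_len(cfg@n_residual_blocks))
    put(paste0("res", k), init_residual_params(cfg@residual_filters, hp))
  cin <- cfg@residual_filters
  for (k in seq_along(df)) {
    f_l <- ef[ne - k]                       # channels of the gated skip
    f_g <- cin                              # gating signal channels
    put(paste0("ag", k),
        init_attention_params(f_l, f_g, cfg@attention_int[k], hp))
    put(paste0("dec", k), init_decoder_params(cin, df[k], hp))
    cin <- df[k] + f_l * (if (dual_skips) 2L else 1L)
  }
  put("head", init_head_params(cin, cfg@output_channels, hp))
  penv
}

# Wrap every parameter of a net as a tape leaf; returns the flat
# name -> node map plus the same nodes grouped by block prefix.
wrap_net_params <- function(tape, penv) {
  nms <- ls(penv)
  flat <- stats::setNames(
    lapply(nms, function(nm) tp_leaf(tape, get(nm, envir = penv))), nms)
  grouped <- list()
  for (nm in nms) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    grouped[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  list(flat = flat, grouped = grouped)
}

# Graph of one network. ext_ags (the other network's attention-gate
# outputs, deepest first) makes each decoder block concatenate the gated
# skips of BOTH networks.
single_net_graph <- function(tape, x, grouped, state, cfg, training,
                             ext_ags = NULL) {
  hp <- cfg@hyper
  ne <- length(cfg@encoder_filters)
  d <- dim(x$value)
  div <- 2L^ne
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("input spatial dims must be divisible by ", div,
         " (got ", d[1], "x", d[2], "); pad first (see padToMultiple)")
  enc <- vector("list", ne)
  h <- x
  for (i in seq_len(ne)) {
    h <- op_encoder_block(tape, h, grouped[[paste0("enc", i)]], hp,
                          state, paste0("enc", i), training)
    enc[[i]] <- h
  }
  for (k in seq_len(cfg@n_residual_blocks))
    h <- op_residual_block(tape, h, grouped[[paste0("res", k)]], hp,
                           state, paste0("res", k), training)
  nd <- length(cfg@decoder_filters)
  ags <- vector("list", nd)
  for (k in seq_len(nd)) {
    ag <- op_attention_gate(tape, enc[[ne - k]], h,
                            grouped[[paste0("ag", k)]], cfg@upsample_mode)
    ags[[k]] <- ag
    skips <- if (is.null(ext_ags)) list(ag$gated)
             else list(ext_ags[[k]]$gated, ag$gated)
    h <- op_decoder_block(tape, h, skips, grouped[[paste0("dec", k)]], hp,
                          state, paste0("dec", k), training)
  }
  list(out = op_output_head(tape, h, grouped$head), ags = ags,
       encoder = enc)
}

# Full double-network graph on one tape. Returns out1/out2 nodes and the
# flat parameter-node maps of both nets (names prefixed net1./net2.).
double_net_graph <- function(tape, x, model, training) {
  cfg <- model@config
  w1 <- wrap_net_params(tape, model@net1@params)
  w2 <- wrap_net_params(tape, model@net2@params)
  r1 <- single_net_graph(tape, x, w1$grouped, model@net1@state, cfg, training)
  xin2 <- tp_mul_alpha(tape, x, r1$out)   # element-wise re-weighting by the salient map
  r2 <- single_net_graph(tape, xin2, w2$grouped, model@net2@state, cfg,
                         training, ext_ags = r1$ags)
  pn <- c(stats::setNames(w1$flat, paste0("net1.", names(w1$flat))),
          stats::setNames(w2$flat, paste0("net2.", names(w2$flat))))
  list(out1 = r1$out, out2 = r2$out, params = pn, net1 = r1, net2 = r2)
}

#' Build one attention-gated residual U-Net
#'
#' Assembles a single network: the stride-2 encoder stack, the residual
#' bottleneck, one attention gate per decoder scale, the decoder stack,
#' and the sigmoid output head, with weights drawn from a zero-mean
#' normal (sd `cfg@hyper@init_std`). Run it with [forwardSingleNet()].
#'
#' @param cfg a [NetworkConfig-class].
#' @param in_channels input image channels (default 1, grayscale).
#' @param seed optional integer; when given, initialization is seeded and
#'   reproducible.
#' @param dual_skips internal: reserve decoder input channels for a
#'   second network's gated skips (used by [assembleDoubleNet()]).
#' @return A [SingleNetModel-class].
#' @export
#' @examples
#' net <- buildSingleNet(networkConfig(encoder_filters = c(2, 4, 6, 8, 10),
#'                                     decoder_filters = c(8, 6, 4, 2)),
#'                       seed = 1)
#' countParameters(net)
buildSingleNet <- function(cfg, in_channels = 1L, seed = NULL,
                           dual_skips = FALSE) {
  validObject(cfg)
  runner <- function() {
    new("SingleNetModel", config = cfg,
        params = init_single_net_params(cfg, in_channels, dual_skips),
        state = new.env(parent = emptyenv()))
  }
  if (is.null(seed)) runner() else with_seed_(seed, runner())
}

#' Run a single network forward
#'
#' @param net a [SingleNetModel-class].
#' @param x input feature map, (1, height, width, channels) array or a
#'   plain matrix; spatial dims must be divisible by 2^(encoder levels).
#' @param training logical; batch statistics and dropout if TRUE.
#' @return list with `out` (the (1, h, w, 1) probability map) and `ags`,
#'   the per-scale attention-gated skip feature maps (deepest first) for
#'   cross-network reuse.
#' @export
forwardSingleNet <- function(net, x, training = FALSE) {
  xv <- fm_in(x)
  tp <- new_tape()
  w <- wrap_net_params(tp, net@params)
  r <- single_net_graph(tp, tp_leaf(tp, xv), w$grouped, net@state,
                        net@config, training)
  list(out = fm_out(r$out$value),
       ags = lapply(r$ags, function(a) fm_out(a$gated$value)),
       alphas = lapply(r$ags, function(a) fm_out(a$alpha$value)),
       encoder_dims = lapply(r$encoder, function(e) dim(e$value)))
}

#' Assemble the double attention residual U-Net
#'
#' Builds both networks from one template with independent weights. At
#' run time the second network receives the input multiplied element-wise
#' by the first network's salient output, and every decoder block of the
#' second network concatenates the attention-gate outputs of both
#' networks at its scale, so gradients from the final output reach every
#' parameter of both networks.
#'
#' @param cfg a [NetworkConfig-class].
#' @param in_channels input image channels (default 1).
#' @param seed optional integer for reproducible initialization.
#' @return A [DoubleNetModel-class].
#' @export
#' @examples
#' cfg <- networkConfig(encoder_filters = c(2, 4, 6, 8, 10),
#'                      decoder_filters = c(8, 6, 4, 2))
#' model <- assembleDoubleNet(cfg, seed = 1)
#' pred <- predictPair(model, matrix(rnorm(64 * 64), 64))
#' range(segmentationMap(pred))   # strictly inside (0, 1)
assembleDoubleNet <- function(cfg, in_channels = 1L, seed = NULL) {
  validObject(cfg)
  runner <- function() {
    new("DoubleNetModel", config = cfg,
        net1 = buildSingleNet(cfg, in_channels),
        net2 = buildSingleNet(cfg, in_channels, dual_skips = TRUE))
  }
  if (is.null(seed)) runner() else with_seed_(seed, runner())
}

#' Forward pass of the double network
#'
#' @param model a [DoubleNetModel-class].
#' @param x input image: a matrix or (1, h, w, c) array with spatial dims
#'   divisible by 2^(encoder levels).
#' @param training logical.
#' @return A [PredictionPair-class]: the salient map of the first network
#'   and the final segmentation probability map.
#' @export
predictPair <- function(model, x, training = FALSE) {
  xv <- fm_in(x)
  tp <- new_tape()
  r <- double_net_graph(tp, tp_leaf(tp, xv), model, training)
  new("PredictionPair", out1 = r$out1$value[, , 1L],
      out2 = r$out2$value[, , 1L])
}

#' Count trainable parameters
#'
#' The exact number of trainable scalars: convolution kernels and biases
#' plus 2 x channels per batch-norm layer (scale and shift); batch-norm
#' running statistics are excluded.
#'
#' @param model a [SingleNetModel-class] or [DoubleNetModel-class].
#' @return integer count.
#' @export
setGeneric("countParameters", function(model) standardGeneric("countParameters"))

#' @rdname countParameters
setMethod("countParameters", "SingleNetModel", function(model) {
  sum(vapply(ls(model@params),
             function(nm) length(get(nm, envir = model@params)), numeric(1)))
})

#' @rdname countParameters
setMethod("countParameters", "DoubleNetModel", function(model) {
  countParameters(model@net1) + countParameters(model@net2)
})

# Deep-copy a model (parameter environments are reference semantics).
copy_env <- function(e) {
  e2 <- new.env(parent = emptyenv())
  for (nm in ls(e)) assign(nm, get(nm, envir = e), e2)
  e2
}

copy_model <- function(model) {
  new("DoubleNetModel", config = model@config,
      net1 = new("SingleNetModel", config = model@config,
                 params = copy_env(model@net1@params),
                 state = copy_env(model@net1@state)),
      net2 = new("SingleNetModel", config = model@config,
                 params = copy_env(model@net2@params),
                 state = copy_env(model@net2@state)))
}

# Run thunk under a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
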