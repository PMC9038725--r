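# Training engine: Adam optimization of the minus-Dice objective at
# batch size 1, per-epoch logging, padded prediction, dataset
# evaluation, and binary checkpoints with an embedded JSON header.

adam_init <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list()
  st$v <- list()
  st
}

adam_step <- function(penv_by_net, grads, st, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- if (is.null(st$m[[nm]])) g * 0 else st$m[[nm]]
    v <- if (is.null(st$v[[nm]])) g * 0 else st$v[[nm]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    net <- substr(nm, 1L, 4L)                 # "net1" / "net2"
    key <- substr(nm, 6L, nchar(nm))
    pe <- penv_by_net[[net]]
    assign(key, get(key, envir = pe) - lr * (m / bc1) / (sqrt(v / bc2) + eps), pe)
  }
}

# Standardize + pad one sample for the network (both are no-ops when
# already applied: z-scoring is idempotent and padding of divisible dims
# adds nothing).
prepare_sample <- function(sample, m = 32L) {
  std <- standardizeImage(sample@image)
  p <- padToMultiple(std$image, m)
  mp <- padToMultiple(sample@mask, m)
  list(x = array(p$image, c(dim(p$image), 1L)),
       target = array(mp$image, c(dim(mp$image), 1L)),
       spec = p$spec)
}

#' Train the double network with Adam on the minus-Dice objective
#'
#' Per-step objective: `diceLoss(out2) + lambda * diceLoss(out1)` where
#' `lambda = cfg@aux_loss_weight` is the auxiliary supervision weight on
#' the first network's salient output. Optimization is Adam (beta1 0.9,
#' beta2 0.999, eps 1e-7) at batch size 1 with a per-epoch reshuffle
#' drawn from the run seed. Samples are standardized and padded to a
#' multiple of 32 internally (both operations are idempotent).
#'
#' @param model a [DoubleNetModel-class]; not modified -- the trained
#'   copy is returned.
#' @param samples training samples: a list of
#'   [SegmentationSample-class] or a [DatasetSplit-class] (its test part
#'   is then used for validation).
#' @param cfg a [TrainConfig-class].
#' @param validation optional list of validation samples.
#' @param keep_best if TRUE and validation samples exist, return the
#'   weights of the epoch with the best validation Dice instead of the
#'   last (off by default; the published protocol trains a fixed number
#'   of epochs).
#' @param verbose print a line per epoch.
#' @return list with `model` (trained) and `log`, a data.frame with one
#'   row per epoch: epoch, train_loss (the full objective, in
#'   \[-(1+lambda), 0\]), train_dice, val_loss, val_dice.
#' @export
trainModel <- function(model, samples, cfg = trainConfig(),
                       validation = NULL, keep_best = FALSE,
                       verbose = FALSE) {
  validObject(cfg)
  if (is(samples, "DatasetSplit")) {
    if (is.null(validation)) validation <- samples@test
    samples <- samples@train
  }
  if (length(samples) < 1L) stop("no training samples")
  model <- copy_model(model)
  prep <- lapply(samples, prepare_sample)
  prep_val <- lapply(validation, prepare_sample)
  lam <- cfg@aux_loss_weight
  penv_by_net <- list(net1 = model@net1@params, net2 = model@net2@params)
  opt <- adam_init()
  n <- length(prep)
  log <- data.frame(epoch = seq_len(cfg@epochs), train_loss = NA_real_,
                    train_dice = NA_real_, val_loss = NA_real_,
                    val_dice = NA_real_)
  run_epochs <- function() {
    best <- list(dice = -Inf, model = NULL)
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      ep_loss <- ep_dice <- 0
      for (i in ord) {
        tp <- new_tape()
        x <- tp_leaf(tp, prep[[i]]$x)
        g <- double_net_graph(tp, x, model, training = TRUE)
        l2 <- tp_dice_loss(tp, g$out2, prep[[i]]$target)
        loss <- if (lam > 0)
          tp_add_scaled(tp, l2, tp_dice_loss(tp, g$out1, prep[[i]]$target), lam)
        else l2
        if (!is.finite(loss$value))
          stop("non-finite loss at epoch ", ep, ", sample ", i,
               " (loss = ", loss$value, ")")
        tape_backward(tp, loss)
        grads <- lapply(g$params, function(nd) nd$grad)
        adam_step(penv_by_net, grads, opt, cfg@learning_rate)
        ep_loss <- ep_loss + loss$value
        ep_dice <- ep_dice - l2$value
      }
      log$train_loss[ep] <<- ep_loss / n
      log$train_dice[ep] <<- ep_dice / n
      if (length(prep_val)) {
        vd <- vapply(prep_val, function(pv) {
          pr <- predictPair(model, fm_out(pv$x))
          softDice(pr@out2, pv$target[, , 1L])
        }, numeric(1))
        log$val_dice[ep] <<- mean(vd)
        log$val_loss[ep] <<- -mean(vd)
        if (keep_best && mean(vd) > best$dice)
          best <- list(dice = mean(vd), model = copy_model(model))
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  dice %.4f%s", ep,
                        log$train_loss[ep], log$train_dice[ep],
                        if (length(prep_val))
                          sprintf("  val dice %.4f", log$val_dice[ep]) else ""))
    }
    if (keep_best && !is.null(best$model)) best$model else model
  }
  model <- if (cfg@deterministic) with_seed_(cfg@seed, run_epochs())
           else run_epochs()
  list(model = model, log = log)
}

#' Segment one image
#'
#' Standardizes the image, zero-pads it to a multiple of 32, runs the
#' double network in inference mode, crops both outputs back to the
#' input size, and thresholds the final probability map.
#'
#' @param model a trained [DoubleNetModel-class].
#' @param image numeric matrix (raw or standardized; standardization is
#'   idempotent).
#' @param threshold binarization threshold (default 0.5).
#' @return list with `pred` (a [PredictionPair-class] at the input's
#'   size) and `mask` (the binarized segmentation).
#' @export
predictSegmentation <- function(model, image, threshold = 0.5) {
  std <- standardizeImage(image)
  p <- padToMultiple(std$image, 2L^length(model@config@encoder_filters))
  pair <- predictPair(model, p$image)
  out1 <- cropBack(pair@out1, p$spec)
  out2 <- cropBack(pair@out2, p$spec)
  list(pred = new("PredictionPair", out1 = out1, out2 = out2),
       mask = binarize(out2, threshold))
}

#' Evaluate a model over a sample list
#'
#' Runs [predictSegmentation()] on every sample and scores the binarized
#' prediction against the ground truth with [hardDice()], [jaccard()]
#' and [hausdorffDistance()] (in mm when the sample carries a pixel
#' spacing). Undefined Hausdorff distances (an empty contour on either
#' side) are reported as NA, excluded from the mean, and counted.
#'
#' @param model a trained [DoubleNetModel-class].
#' @param samples list of [SegmentationSample-class].
#' @param threshold binarization threshold.
#' @return A [MetricReport-class].
#' @export
evaluateModel <- function(model, samples, threshold = 0.5) {
  res <- lapply(samples, function(s) {
    pred <- predictSegmentation(model, s@image, threshold)$mask
    hd <- tryCatch(
      hausdorffDistance(extractContour(pred), extractContour(s@mask),
                        spacing = s@spacing),
      error = function(e) NA_real_)
    c(dsc = hardDice(pred, s@mask), jsc = jaccard(pred, s@mask), hd = hd)
  })
  m <- do.call(rbind, res)
  metricReport(vapply(samples, sampleId, character(1)),
               m[, "dsc"], m[, "jsc"], m[, "hd"])
}

#' Write a training log as CSV
#'
#' @param log the data.frame returned by [trainModel()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrainLog <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

# -- checkpoints ------------------------------------------------------------

network_config_as_list <- function(cfg) {
  list(encoder_filters = cfg@encoder_filters,
       decoder_filters = cfg@decoder_filters,
       n_residual_blocks = cfg@n_residual_blocks,
       residual_filters = cfg@residual_filters,
       attention_int = cfg@attention_int,
       output_channels = cfg@output_channels,
       upsample_mode = cfg@upsample_mode,
       kernel_size = cfg@hyper@kernel_size,
       stride = cfg@hyper@stride,
       init_std = cfg@hyper@init_std,
       leaky_slope = cfg@hyper@leaky_slope,
       dropout_rate = cfg@hyper@dropout_rate)
}

network_config_from_list <- function(l) {
  networkConfig(encoder_filters = l$encoder_filters,
                decoder_filters = l$decoder_filters,
                n_residual_blocks = l$n_residual_blocks,
                residual_filters = l$residual_filters,
                attention_int = l$attention_int,
                output_channels = l$output_channels,
                upsample_mode = l$upsample_mode,
                hyper = layerHyperParams(kernel_size = l$kernel_size,
                                         stride = l$stride,
                                         init_std = l$init_std,
                                         leaky_slope = l$leaky_slope,
                                         dropout_rate = l$dropout_rate))
}

ckpt_order <- function(model) {
  items <- list()
  for (net in c("net1", "net2")) {
    pe <- slot(model, net)@params
    for (nm in sort(ls(pe)))
      items[[length(items) + 1L]] <-
        list(kind = "param", net = net, name = nm,
             dim = dim(get(nm, envir = pe)) %||% length(get(nm, envir = pe)))
    se <- slot(model, net)@state
    for (nm in sort(ls(se)))
      items[[length(items) + 1L]] <-
        list(kind = "state", net = net, name = nm,
             dim = length(se[[nm]]$mean))
  }
  items
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load model checkpoints
#'
#' A checkpoint is a single binary file: a JSON header (format version,
#' the [NetworkConfig-class], epoch, seed, and the tensor catalogue)
#' followed by all parameter values and batch-norm running statistics as
#' raw doubles. The round trip is bit-exact, so inference outputs before
#' and after save/load are identical.
#'
#' @param model a [DoubleNetModel-class].
#' @param path checkpoint file path.
#' @param epoch,seed metadata recorded for resumption.
#' @return `saveCheckpoint`: the path, invisibly. `loadCheckpoint`: the
#'   restored [DoubleNetModel-class] with attributes `epoch` and `seed`.
#' @export
saveCheckpoint <- function(model, path, epoch = NA_integer_,
                           seed = NA_integer_) {
  items <- ckpt_order(model)
  header <- list(magic = "daresunet-checkpoint", version = 1L,
                 epoch = epoch, seed = seed,
                 network = network_config_as_list(model@config),
                 tensors = items)
  hraw <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (it in items) {
    net <- slot(model, it$net)
    if (it$kind == "param") {
      writeBin(as.double(get(it$name, envir = net@params)), con,
               endian = "little")
    } else {
      rs <- net@state[[it$name]]
      writeBin(as.double(c(rs$mean, rs$var)), con, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param config optional [NetworkConfig-class]; when supplied it must
#'   match the checkpointed one exactly, otherwise loading errors.
#' @export
loadCheckpoint <- function(path, config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(header$magic, "daresunet-checkpoint") ||
      !identical(header$version, 1L))
    stop("not a recognized checkpoint file: ", path)
  cfg <- network_config_from_list(header$network)
  if (!is.null(config) &&
      !identical(network_config_as_list(config), network_config_as_list(cfg)))
    stop("checkpoint NetworkConfig does not match the requested one")
  model <- assembleDoubleNet(cfg, seed = 0L)
  for (it in header$tensors) {
    net <- slot(model, it$net)
    if (it$kind == "param") {
      n <- prod(it$dim)
      v <- readBin(con, "double", n, endian = "little")
      assign(it$name, if (length(it$dim) > 1L) array(v, it$dim) else v,
             envir = net@params)
    } else {
      v <- readBin(con, "double", 2L * it$dim, endian = "little")
      net@state[[it$name]] <- list(mean = v[seq_len(it$dim)],
                                   var = v[it$dim + seq_len(it$dim)])
    }
  }
  attr(model, "epoch") <- header$epoch
  attr(model, "seed") <- header$seed
  model
}
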