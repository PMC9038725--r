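#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Layer hyper-parameters shared across the network
#'
#' Holds the per-layer settings used throughout both networks: the 5x5
#' convolution kernel, the 2x2 resampling stride (residual blocks always
#' use stride 1), the 0.02 standard deviation of the zero-mean normal
#' weight initialization, the 0.2 negative slope of the leaky rectifier
#' in the encoder, and the 30% decoder dropout. Padding is always "same"
#' (output spatial size = ceil(input / stride)).
#'
#' @slot kernel_size integer(2), convolution kernel height/width.
#' @slot stride integer(2), encoder/decoder resampling stride.
#' @slot init_std numeric, SD of the normal weight initialization.
#' @slot leaky_slope numeric, negative slope of the leaky rectifier.
#' @slot dropout_rate numeric, decoder dropout probability.
#' @slot padding character, padding mode (only "same" is supported).
#' @exportClass LayerHyperParams
setClass("LayerHyperParams",
  representation(kernel_size = "integer", stride = "integer",
                 init_std = "numeric", leaky_slope = "numeric",
                 dropout_rate = "numeric", padding = "character"),
  prototype(kernel_size = c(5L, 5L), stride = c(2L, 2L),
            init_std = 0.02, leaky_slope = 0.2,
            dropout_rate = 0.3, padding = "same"))

setValidity("LayerHyperParams", function(object) {
  msg <- character()
  if (any(object@kernel_size < 1L)) msg <- c(msg, "kernel_size components must be >= 1")
  if (object@dropout_rate < 0 || object@dropout_rate >= 1)
    msg <- c(msg, "dropout_rate must be in [0, 1)")
  if (object@init_std <= 0) msg <- c(msg, "init_std must be > 0")
  if (object@leaky_slope < 0 || object@leaky_slope >= 1)
    msg <- c(msg, "leaky_slope must be in [0, 1)")
  if (!identical(object@padding, "same")) msg <- c(msg, "padding must be \"same\"")
  if (length(msg)) msg else TRUE
})

#' Constructor for [LayerHyperParams-class]
#'
#' @param kernel_size,stride,init_std,leaky_slope,dropout_rate see the
#'   class slots; defaults are the published settings (5x5 kernel, 2x2
#'   stride, 0.02 init SD, 0.2 slope, 0.3 dropout).
#' @return A `LayerHyperParams` object.
#' @export
#' @examples
#' layerHyperParams()
layerHyperParams <- function(kernel_size = c(5L, 5L), stride = c(2L, 2L),
                             init_std = 0.02, leaky_slope = 0.2,
                             dropout_rate = 0.3) {
  new("LayerHyperParams", kernel_size = as.integer(kernel_size),
      stride = as.integer(stride), init_std = init_std,
      leaky_slope = leaky_slope, dropout_rate = dropout_rate)
}

#' Full architecture description of one attention-gated residual U-Net
#'
#' Describes one of the two identical network templates: five stride-2
#' encoder blocks (default filters 20, 40, 80, 160, 320), a stack of four
#' residual blocks at the bottleneck (320 filters), four transposed-conv
#' decoder blocks (160, 80, 40, 20) each concatenating an attention-gated
#' skip, and a transposed-conv sigmoid output head. `attention_int` gives
#' the per-gate intermediate channel count (default: half the gated skip's
#' channels, minimum 1).
#'
#' @slot encoder_filters integer, channel counts of the encoder blocks.
#' @slot decoder_filters integer, channel counts of the decoder blocks.
#' @slot n_residual_blocks integer, residual blocks at the bottleneck.
#' @slot residual_filters integer, channels inside the residual blocks.
#' @slot attention_int integer, per-gate intermediate channels (deepest first).
#' @slot output_channels integer, output head channels (1 = binary mask).
#' @slot upsample_mode character, gate upsampling: "bilinear" or "nearest".
#' @slot hyper a [LayerHyperParams-class].
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(encoder_filters = "integer", decoder_filters = "integer",
                 n_residual_blocks = "integer", residual_filters = "integer",
                 attention_int = "integer", output_channels = "integer",
                 upsample_mode = "character", hyper = "LayerHyperParams"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (length(object@encoder_filters) != length(object@decoder_filters) + 1L)
    msg <- c(msg, "need length(encoder_filters) == length(decoder_filters) + 1")
  if (object@n_residual_blocks < 1L) msg <- c(msg, "n_residual_blocks must be >= 1")
  if (any(c(object@encoder_filters, object@decoder_filters,
            object@residual_filters, object@output_channels,
            object@attention_int) <= 0L))
    msg <- c(msg, "all channel counts must be > 0")
  if (length(object@attention_int) != length(object@decoder_filters))
    msg <- c(msg, "attention_int needs one entry per decoder block")
  if (!object@upsample_mode %in% c("bilinear", "nearest"))
    msg <- c(msg, "upsample_mode must be \"bilinear\" or \"nearest\"")
  if (length(msg)) msg else TRUE
})

#' Constructor for [NetworkConfig-class]
#'
#' @param encoder_filters,decoder_filters channel progressions; defaults
#'   are the published 20/40/80/160/320 and 160/80/40/20.
#' @param n_residual_blocks bottleneck depth (default 4).
#' @param residual_filters channels in the residual stack; defaults to the
#'   deepest encoder width.
#' @param attention_int intermediate gate channels, deepest gate first;
#'   default is half the gated encoder level's channels (minimum 1).
#' @param output_channels output head channels (default 1).
#' @param upsample_mode gate upsampling mode, "bilinear" (default) or
#'   "nearest".
#' @param hyper a [LayerHyperParams-class].
#' @return A `NetworkConfig` object.
#' @export
#' @examples
#' networkConfig()                                   # published widths
#' networkConfig(encoder_filters = c(4, 8, 16, 32, 64),
#'               decoder_filters = c(32, 16, 8, 4))  # reduced width
networkConfig <- function(encoder_filters = c(20L, 40L, 80L, 160L, 320L),
                          decoder_filters = c(160L, 80L, 40L, 20L),
                          n_residual_blocks = 4L,
                          residual_filters = NULL,
                          attention_int = NULL,
                          output_channels = 1L,
                          upsample_mode = "bilinear",
                          hyper = layerHyperParams()) {
  encoder_filters <- as.integer(encoder_filters)
  decoder_filters <- as.integer(decoder_filters)
  if (is.null(residual_filters))
    residual_filters <- encoder_filters[length(encoder_filters)]
  if (is.null(attention_int)) {
    ne <- length(encoder_filters)
    # gate k (deepest first) rescales encoder level ne-k's features
    gated <- encoder_filters[seq.int(ne - 1L, 1L)]
    attention_int <- pmax(1L, gated %/% 2L)
  }
  new("NetworkConfig", encoder_filters = encoder_filters,
      decoder_filters = decoder_filters,
      n_residual_blocks = as.integer(n_residual_blocks),
      residual_filters = as.integer(residual_filters),
      attention_int = as.integer(attention_int),
      output_channels = as.integer(output_channels),
      upsample_mode = upsample_mode, hyper = hyper)
}

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig (attention-gated residual U-Net template)\n")
  cat("  encoder filters:  ", paste(object@encoder_filters, collapse = ", "), "\n")
  cat("  decoder filters:  ", paste(object@decoder_filters, collapse = ", "), "\n")
  cat("  residual blocks:  ", object@n_residual_blocks, "x",
      object@residual_filters, "filters\n")
  cat("  attention F_int:  ", paste(object@attention_int, collapse = ", "),
      "(deepest gate first)\n")
  cat("  gate upsampling:  ", object@upsample_mode, "\n")
})

#' One network of the double architecture
#'
#' The weights and batch-norm running statistics of a single
#' attention-gated residual U-Net, as assembled by [buildSingleNet()].
#'
#' @slot config the [NetworkConfig-class] it was built from.
#' @slot params environment mapping parameter names to arrays.
#' @slot state environment holding batch-norm running statistics.
#' @exportClass SingleNetModel
setClass("SingleNetModel",
  representation(config = "NetworkConfig", params = "environment",
                 state = "environment"))

setMethod("show", "SingleNetModel", function(object) {
  cat("SingleNetModel:", length(ls(object@params)), "parameter tensors,",
      countParameters(object), "trainable scalars\n")
})

#' The assembled double network
#'
#' Two structurally identical single networks with independent weights.
#' The second network segments the input re-weighted by the first
#' network's salient map and its decoder concatenates the attention-gate
#' outputs of BOTH networks at each scale. Assemble with
#' [assembleDoubleNet()], train with [trainModel()], run with
#' [predictPair()] or [predictSegmentation()].
#'
#' @slot config the shared [NetworkConfig-class] template.
#' @slot net1,net2 the two [SingleNetModel-class] instances.
#' @exportClass DoubleNetModel
setClass("DoubleNetModel",
  representation(config = "NetworkConfig", net1 = "SingleNetModel",
                 net2 = "SingleNetModel"))

setMethod("show", "DoubleNetModel", function(object) {
  cat("DoubleNetModel (double attention residual U-Net)\n")
  cat("  encoder filters:", paste(object@config@encoder_filters, collapse = ", "), "\n")
  cat("  trainable parameters:", countParameters(object), "\n")
})

#' Paired outputs of the double network
#'
#' `out1` is the first network's salient map (a soft highlight of the
#' target), `out2` the final segmentation probability map. Both are
#' probability matrices of the input's spatial size with entries strictly
#' in (0, 1).
#'
#' @slot out1,out2 numeric matrices in (0, 1).
#' @exportClass PredictionPair
setClass("PredictionPair",
  representation(out1 = "matrix", out2 = "matrix"))

setValidity("PredictionPair", function(object) {
  if (!all(dim(object@out1) == dim(object@out2)))
    return("out1 and out2 must have identical spatial size")
  TRUE
})

setMethod("show", "PredictionPair", function(object) {
  cat("PredictionPair:", nrow(object@out1), "x", ncol(object@out1),
      "salient + segmentation probability maps\n")
})

#' Salient map accessor
#' @param x a [PredictionPair-class]
#' @return the requested probability matrix.
#' @export
salientMap <- function(x) x@out1

#' Segmentation probability map accessor
#' @rdname salientMap
#' @export
segmentationMap <- function(x) x@out2

#' One image/mask pair
#'
#' The unit every pipeline operates on: a real-valued image grid, a
#' binary mask of the same size, an identifier, and an optional pixel
#' spacing in mm/px used to report Hausdorff distances and lengths in
#' millimetres.
#'
#' @slot image numeric matrix (rows = height).
#' @slot mask numeric matrix with entries in {0, 1}.
#' @slot id character identifier.
#' @slot spacing numeric mm/px, or NULL when unknown.
#' @exportClass SegmentationSample
setClass("SegmentationSample",
  representation(image = "matrix", mask = "matrix", id = "character",
                 spacing = "numericOrNULL"),
  prototype(spacing = NULL))

setValidity("SegmentationSample", function(object) {
  msg <- character()
  if (!all(dim(object@image) == dim(object@mask)))
    msg <- c(msg, "image and mask must have the same shape")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Constructor for [SegmentationSample-class]
#' @param image,mask,id,spacing see the class slots.
#' @return A `SegmentationSample`.
#' @export
segmentationSample <- function(image, mask, id, spacing = NULL) {
  new("SegmentationSample", image = image, mask = mask,
      id = as.character(id), spacing = spacing)
}

setMethod("show", "SegmentationSample", function(object) {
  cat("SegmentationSample", object@id, ":", nrow(object@image), "x",
      ncol(object@image), "; foreground px:", sum(object@mask),
      if (!is.null(object@spacing)) paste0("; spacing ", object@spacing, " mm/px"),
      "\n")
})

#' Sample image / mask / id accessors
#' @param x a [SegmentationSample-class]
#' @return the requested slot value.
#' @export
sampleImage <- function(x) x@image
#' @rdname sampleImage
#' @export
sampleMask <- function(x) x@mask
#' @rdname sampleImage
#' @export
sampleId <- function(x) x@id
#' @rdname sampleImage
#' @export
sampleSpacing <- function(x) x@spacing

#' A seeded train/test partition
#'
#' @slot train,test lists of [SegmentationSample-class].
#' @slot seed integer seed of the shuffle.
#' @slot test_fraction proportion held out.
#' @exportClass DatasetSplit
setClass("DatasetSplit",
  representation(train = "list", test = "list", seed = "integer",
                 test_fraction = "numeric"))

setMethod("show", "DatasetSplit", function(object) {
  cat("DatasetSplit:", length(object@train), "train /", length(object@test),
      "test (fraction", object@test_fraction, ", seed", object@seed, ")\n")
})

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-4,
#' batch size 1, minus-Dice objective. `aux_loss_weight` is the weight of
#' the auxiliary minus-Dice term on the first network's salient output
#' (0 trains on the final output only).
#'
#' @slot learning_rate numeric.
#' @slot batch_size integer (only 1 is supported).
#' @slot epochs integer.
#' @slot aux_loss_weight numeric >= 0.
#' @slot seed integer.
#' @slot deterministic logical; seed the run for exact reproducibility.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learning_rate = "numeric", batch_size = "integer",
                 epochs = "integer", aux_loss_weight = "numeric",
                 seed = "integer", deterministic = "logical"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learning_rate <= 0) msg <- c(msg, "learning_rate must be > 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batch_size != 1L) msg <- c(msg, "only batch_size = 1 is supported")
  if (object@aux_loss_weight < 0) msg <- c(msg, "aux_loss_weight must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Constructor for [TrainConfig-class]
#' @param learning_rate,batch_size,epochs,aux_loss_weight,seed,deterministic
#'   see the class slots.
#' @return A `TrainConfig`.
#' @export
#' @examples
#' trainConfig(epochs = 150)
trainConfig <- function(learning_rate = 1e-4, batch_size = 1L,
                        epochs = 150L, aux_loss_weight = 0.5,
                        seed = 1L, deterministic = TRUE) {
  new("TrainConfig", learning_rate = learning_rate,
      batch_size = as.integer(batch_size), epochs = as.integer(epochs),
      aux_loss_weight = aux_loss_weight, seed = as.integer(seed),
      deterministic = deterministic)
}

#' Per-sample and aggregate segmentation metrics
#'
#' @slot per_sample data.frame with columns id, dsc, jsc, hd (hd is NA
#'   where undefined, i.e. an empty contour on either side).
#' @slot summary data.frame with rows mean, sd per metric.
#' @slot n integer, number of samples.
#' @slot hd_undefined integer, samples whose Hausdorff distance was
#'   undefined and excluded from the summary.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(per_sample = "data.frame", summary = "data.frame",
                 n = "integer", hd_undefined = "integer"))

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport over", object@n, "samples",
      if (object@hd_undefined > 0L)
        paste0("(", object@hd_undefined, " undefined HD)"), "\n")
  print(object@summary, digits = 4)
})

#' Metric report accessors
#' @param x a [MetricReport-class]
#' @return `perSampleMetrics`: the per-sample data.frame;
#'   `metricSummary`: the mean/sd summary data.frame.
#' @export
perSampleMetrics <- function(x) x@per_sample
#' @rdname perSampleMetrics
#' @export
metricSummary <- function(x) x@summary

#' Bland-Altman agreement statistics
#'
#' @slot bias mean difference (automatic - manual).
#' @slot sd sample standard deviation of the differences.
#' @slot loa_low,loa_high bias -/+ 1.96 sd limits of agreement.
#' @slot n number of measurement pairs.
#' @exportClass BlandAltmanResult
setClass("BlandAltmanResult",
  representation(bias = "numeric", sd = "numeric", loa_low = "numeric",
                 loa_high = "numeric", n = "integer"))

setValidity("BlandAltmanResult", function(object) {
  if (object@loa_low > object@bias || object@bias > object@loa_high)
    return("limits of agreement must bracket the bias")
  TRUE
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f, LoA [%.4f, %.4f]\n",
              object@n, object@bias, object@loa_low, object@loa_high))
})

#' Box-whisker summary of a metric distribution
#'
#' Quartiles by linear interpolation between order statistics, Tukey
#' fences at 1.5 IQR, whiskers at the extreme data inside the fences.
#'
#' @slot median,q1,q3,whisker_low,whisker_high numeric.
#' @slot outliers numeric, values outside the whisker interval.
#' @exportClass WhiskerSummary
setClass("WhiskerSummary",
  representation(median = "numeric", q1 = "numeric", q3 = "numeric",
                 whisker_low = "numeric", whisker_high = "numeric",
                 outliers = "numeric"))

setMethod("show", "WhiskerSummary", function(object) {
  cat(sprintf("Whiskers [%.4g | %.4g %.4g %.4g | %.4g], %d outlier(s)\n",
              object@whisker_low, object@q1, object@median, object@q3,
              object@whisker_high, length(object@outliers)))
})

#' Synthetic speckle-phantom configuration
#'
#' Parameters of the ultrasound-like phantom generator: a single bright,
#' soft-edged, deformed-ellipse target on a darker textured background,
#' multiplicative Gamma speckle of unit mean, a top-to-bottom linear
#' attenuation profile, and Gaussian blur. See [generateMask()],
#' [renderImage()], [generateDataset()].
#'
#' @slot height,width canvas size in pixels.
#' @slot n_samples number of image/mask pairs to generate.
#' @slot area_frac length-2 numeric, admissible target area fraction.
#' @slot fg_mean,bg_mean base intensities (image scale 0..1).
#' @slot speckle_shape Gamma shape k of the unit-mean speckle multiplier.
#' @slot blur_sigma Gaussian blur SD in pixels.
#' @slot attenuation fractional intensity drop from top to bottom row.
#' @slot boundary_roughness radial perturbation amplitude of the target.
#' @slot seed integer.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(height = "integer", width = "integer", n_samples = "integer",
                 area_frac = "numeric", fg_mean = "numeric", bg_mean = "numeric",
                 speckle_shape = "numeric", blur_sigma = "numeric",
                 attenuation = "numeric", boundary_roughness = "numeric",
                 seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  af <- object@area_frac
  if (length(af) != 2L || !(0 < af[1] && af[1] < af[2] && af[2] < 1))
    msg <- c(msg, "area_frac must satisfy 0 < min < max < 1")
  if (object@fg_mean == object@bg_mean) msg <- c(msg, "fg_mean must differ from bg_mean")
  if (object@speckle_shape <= 0) msg <- c(msg, "speckle_shape must be > 0")
  if (object@blur_sigma < 0) msg <- c(msg, "blur_sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Constructor for [SynthConfig-class]
#'
#' @param height,width,n_samples,area_frac,fg_mean,bg_mean,speckle_shape,
#'   blur_sigma,attenuation,boundary_roughness,seed see the class slots.
#' @return A `SynthConfig`.
#' @export
#' @examples
#' synthConfig(n_samples = 8, seed = 7)
synthConfig <- function(height = 64L, width = 64L, n_samples = 8L,
                        area_frac = c(0.08, 0.30), fg_mean = 0.70,
                        bg_mean = 0.35, speckle_shape = 4,
                        blur_sigma = 1, attenuation = 0.2,
                        boundary_roughness = 0.15, seed = 1L) {
  new("SynthConfig", height = as.integer(height), width = as.integer(width),
      n_samples = as.integer(n_samples), area_frac = area_frac,
      fg_mean = fg_mean, bg_mean = bg_mean, speckle_shape = speckle_shape,
      blur_sigma = blur_sigma, attenuation = attenuation,
      boundary_roughness = boundary_roughness, seed = as.integer(seed))
}
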