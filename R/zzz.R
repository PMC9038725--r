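#' daresunet: double attention residual U-Net segmentation
#'
#' Two consecutive attention-gated residual U-Nets for binary
#' segmentation of clinical targets, with a self-contained numerical
#' core, minus-Dice training, evaluation metrics, a synthetic
#' speckle-phantom generator and clinical agreement analytics. Start
#' from [assembleDoubleNet()], [trainModel()] and [evaluateModel()], or
#' from the `daresunet` command-line script under `inst/scripts/`.
#'
#' @useDynLib daresunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"
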