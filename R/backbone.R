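# Layer lists for the two backbone topologies. "tiny" is a desk-scale
# two-conv-block network operating directly on 80 x 80 slices;
# "alexnet-conv" follows the five-conv-block AlexNet convolutional stack
# (fully-connected layers truncated), with the slice resized to the native
# 224 input and grayscale replicated to 3 channels, global-average-pooled
# to a 256-vector.
#' @noRd
.backboneSpec <- function(type, cin, D) {
  if (type == "tiny") {
    c1 <- 8L
    list(layers = list(
      list(type = "conv", k = 3L, cin = cin, cout = c1, stride = 1L, pad = 1L),
      list(type = "relu"),
      list(type = "maxpool", f = 4L, stride = 4L),
      list(type = "conv", k = 3L, cin = c1, cout = D, stride = 1L, pad = 1L),
      list(type = "relu"),
      list(type = "maxpool", f = 4L, stride = 4L),
      list(type = "gap")),
      D = D)
  } else if (type == "alexnet-conv") {
    cin1 <- if (cin == 1L) 3L else cin
    list(layers = list(
      list(type = "resize", size = 224L, replicate = cin == 1L),
      list(type = "conv", k = 11L, cin = cin1, cout = 96L, stride = 4L,
           pad = 2L),
      list(type = "relu"),
      list(type = "maxpool", f = 3L, stride = 2L),
      list(type = "conv", k = 5L, cin = 96L, cout = 256L, stride = 1L,
           pad = 2L),
      list(type = "relu"),
      list(type = "maxpool", f = 3L, stride = 2L),
      list(type = "conv", k = 3L, cin = 256L, cout = 384L, stride = 1L,
           pad = 1L),
      list(type = "relu"),
      list(type = "conv", k = 3L, cin = 384L, cout = 384L, stride = 1L,
           pad = 1L),
      list(type = "relu"),
      list(type = "conv", k = 3L, cin = 384L, cout = 256L, stride = 1L,
           pad = 1L),
      list(type = "relu"),
      list(type = "maxpool", f = 3L, stride = 2L),
      list(type = "gap")),
      D = 256L)
  } else stop("unknown backbone type: ", type, call. = FALSE)
}

# He-style initialization of one backbone's weights (RNG stream of the
# caller).
#' @noRd
.backboneInit <- function(spec) {
  lapply(spec$layers, function(L) {
    if (L$type == "conv") {
      fanIn <- L$k * L$k * L$cin
      list(W = matrix(stats::rnorm(fanIn * L$cout, 0, sqrt(2 / fanIn)),
                      fanIn, L$cout),
           b = numeric(L$cout))
    } else NULL
  })
}

#' Extract per-modality backbone features from one slice
#'
#' Runs one modality's slice through that modality's convolutional
#' backbone, yielding the length-D feature vector that enters the fusion
#' block. Deterministic given the model weights.
#'
#' @param model A \linkS4class{FusionModel} (not image-level fusion).
#' @param slice Numeric matrix (80 x 80 for the tiny backbone), values in
#'   [-1, 1].
#' @param modality Canonical modality name selecting the backbone branch.
#' @return Numeric feature vector of length \code{model@D}.
#' @export
backboneFeatures <- function(model, slice, modality) {
  stopifnot(is(model, "FusionModel"))
  checkModality(modality)
  if (model@method == "IMG-F") {
    stop("image-level fusion has a single 7-channel backbone; ",
         "per-modality features are undefined", call. = FALSE)
  }
  if (!is.matrix(slice) || nrow(slice) != model@config$inputSize ||
      ncol(slice) != model@config$inputSize) {
    stop("slice must be a ", model@config$inputSize, " x ",
         model@config$inputSize, " matrix", call. = FALSE)
  }
  x <- array(slice, c(dim(slice), 1L))
  spec <- model@config$spec
  bi <- if (model@config$sharedBackbone) 1L else match(modality, .MODALITIES)
  .nnForward(spec$layers, model@weights$backbones[[bi]], x)$out
}
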