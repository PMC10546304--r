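#' Build a multi-branch fusion network
#'
#' Constructs the seven-branch classification network: one convolutional
#' backbone per modality (optionally shared), a fusion block (MAX, SUM,
#' CAT or the disentanglement fusion DIS), a two-layer fully-connected
#' main classifier, and per-modality secondary classifier heads used both
#' as training supervision and for single-modality evaluation. With
#' \code{method = "IMG-F"} (image-level / early fusion) a single backbone
#' takes the seven slices stacked as a 7-channel image; no secondary heads
#' exist in that mode.
#'
#' @param method Fusion strategy: "SUM", "MAX", "CAT", "DIS" or "IMG-F".
#' @param backbone "tiny" (two small conv blocks on the 80 x 80 slice,
#'   feature length \code{D}) or "alexnet-conv" (five-conv-block stack,
#'   slice resized to 224 and replicated to 3 channels, D forced to 256).
#' @param D Per-modality feature length (tiny backbone only).
#' @param La Appearance length for DIS (0 otherwise).
#' @param hidden Hidden width of every classifier head.
#' @param sharedBackbone If TRUE all seven branches share one weight set;
#'   default FALSE (one independent weight set per modality).
#' @param sharedSecondaryHeads If TRUE the seven secondary heads share
#'   weights; default FALSE (same architecture, independent weights).
#' @param contentMean If TRUE the DIS content parts are averaged instead of
#'   summed; default FALSE (sum).
#' @param seed Integer seed for the (deterministic) random initialization.
#' @return A \linkS4class{FusionModel}.
#' @export
fusionModel <- function(method = c("DIS", "SUM", "MAX", "CAT", "IMG-F"),
                        backbone = c("tiny", "alexnet-conv"),
                        D = 16L, La = 0L, hidden = 32L,
                        sharedBackbone = FALSE,
                        sharedSecondaryHeads = FALSE,
                        contentMean = FALSE, seed = 1L) {
  method <- match.arg(method)
  backbone <- match.arg(backbone)
  D <- as.integer(D); La <- as.integer(La); hidden <- as.integer(hidden)
  if (backbone == "alexnet-conv") D <- 256L
  if (method != "DIS") La <- 0L
  if (La < 0L || La > D) stop("La must lie in [0, D]", call. = FALSE)
  cin <- if (method == "IMG-F") 7L else 1L
  spec <- .backboneSpec(backbone, cin, D)
  withSeed(seed, {
    nBack <- if (method == "IMG-F" || sharedBackbone) 1L else 7L
    backbones <- lapply(seq_len(nBack), function(i) .backboneInit(spec))
    mainHead <- .headInit(fusedLength(method, D, La), hidden)
    secHeads <- if (method == "IMG-F") list() else {
      nSec <- if (sharedSecondaryHeads) 1L else 7L
      lapply(seq_len(nSec), function(i) .headInit(D, hidden))
    }
    new("FusionModel", method = method, backbone = backbone, D = D, La = La,
        hidden = hidden,
        weights = list(backbones = backbones, mainHead = mainHead,
                       secHeads = secHeads),
        config = list(spec = spec, inputSize = 80L, cin = cin,
                      sharedBackbone = sharedBackbone || method == "IMG-F",
                      sharedSecondaryHeads = sharedSecondaryHeads,
                      contentMean = contentMean),
        seed = as.integer(seed))
  })
}

#' @noRd
.fuseVector <- function(model, F) {
  fs <- featureSet(F, model@La)
  f <- switch(model@method,
              "SUM" = fuseSum(fs), "MAX" = fuseMax(fs), "CAT" = fuseCat(fs),
              "DIS" = fuseDis(fs))
  if (model@method == "DIS" && isTRUE(model@config$contentMean) &&
      model@La < model@D) {
    nCon <- model@D - model@La
    idx <- 7L * model@La + seq_len(nCon)
    f[idx] <- f[idx] / 7
  }
  f
}

#' Apply a classifier head to a fused feature
#'
#' Two affine layers with a ReLU between, followed by a two-way softmax.
#' The returned probabilities are in (SCN, MCN) order and sum to 1.
#'
#' @param fused Numeric fused feature vector.
#' @param head Either a \linkS4class{FusionModel} (its main head is used)
#'   or a head weight list (W1, b1, W2, b2).
#' @return Named numeric vector \code{c(pScn=, pMcn=)}.
#' @export
classify <- function(fused, head) {
  if (is(head, "FusionModel")) head <- head@weights$mainHead
  if (length(fused) != nrow(head$W1)) {
    stop("fused feature length ", length(fused),
         " does not match head input size ", nrow(head$W1), call. = FALSE)
  }
  p <- .headForward(head, fused)$p
  c(pScn = p[1], pMcn = p[2])
}

# Full forward pass with caches (training) for one slice pack.
#' @noRd
.forwardSliceFull <- function(model, pack) {
  w <- model@weights
  spec <- model@config$spec
  if (model@method == "IMG-F") {
    x <- pack@slices
    br <- .nnForward(spec$layers, w$backbones[[1L]], x)
    hf <- .headForward(w$mainHead, br$out)
    return(list(F = NULL, backCaches = list(br$caches), feat = br$out,
                main = hf, sec = NULL))
  }
  F <- matrix(0, 7L, model@D)
  backCaches <- vector("list", 7L)
  for (m in seq_len(7L)) {
    bi <- if (model@config$sharedBackbone) 1L else m
    x <- array(pack@slices[, , m], c(dim(pack@slices)[1:2], 1L))
    br <- .nnForward(spec$layers, w$backbones[[bi]], x)
    F[m, ] <- br$out
    backCaches[[m]] <- br$caches
  }
  fused <- .fuseVector(model, F)
  mainF <- .headForward(w$mainHead, fused)
  sec <- vector("list", 7L)
  for (m in seq_len(7L)) {
    si <- if (model@config$sharedSecondaryHeads) 1L else m
    sec[[m]] <- .headForward(w$secHeads[[si]], F[m, ])
  }
  list(F = F, backCaches = backCaches, fused = fused, main = mainF,
       sec = sec)
}

#' Forward pass for one slice pack
#'
#' Computes the main diagnosis probability from the fused feature and, for
#' the feature-level fusion methods, the seven secondary (per-modality)
#' probabilities from each modality's own feature through its secondary
#' head. For image-level fusion (IMG-F) the secondary outputs are absent.
#'
#' @param pack A \linkS4class{SlicePack}.
#' @param model A \linkS4class{FusionModel}.
#' @return List with \code{main} (named c(pScn, pMcn)) and
#'   \code{secondary} (7 x 2 matrix, rows in canonical modality order, or
#'   NULL for IMG-F).
#' @export
forwardSlice <- function(pack, model) {
  stopifnot(is(pack, "SlicePack"), is(model, "FusionModel"))
  if (dim(pack@slices)[1] != model@config$inputSize) {
    stop("pack slice size ", dim(pack@slices)[1],
         " does not match model input size ", model@config$inputSize,
         call. = FALSE)
  }
  r <- .forwardSliceFull(model, pack)
  main <- c(pScn = r$main$p[1], pMcn = r$main$p[2])
  secondary <- NULL
  if (!is.null(r$sec)) {
    secondary <- t(vapply(r$sec, function(s) s$p, numeric(2L)))
    dimnames(secondary) <- list(.MODALITIES, c("pScn", "pMcn"))
  }
  list(main = main, secondary = secondary)
}
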