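#' Loss weighting for end-to-end training
#'
#' @param lambdaAux Weight of the auxiliary (secondary per-modality
#'   cross-entropy) terms.
#' @param lambdaContent Weight of the content-consistency constraint.
#' @param lambdaAppearance Weight of the appearance-separation constraint.
#' @return Named list of nonnegative weights.
#' @export
lossWeights <- function(lambdaAux = 1.0, lambdaContent = 0.1,
                        lambdaAppearance = 0.1) {
  w <- list(lambdaAux = lambdaAux, lambdaContent = lambdaContent,
            lambdaAppearance = lambdaAppearance)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative",
                               call. = FALSE)
  w
}

#' @noRd
.featMatrix <- function(fs) {
  if (is(fs, "FeatureSet")) fs@features else as.matrix(fs)
}

#' Content-consistency loss
#'
#' Constrains the shared content parts of the per-modality features to
#' agree: the mean squared deviation of each modality's content vector
#' from the across-modality mean, normalized by (number of modalities x
#' content length):
#' \code{L_c = (1 / (M * (D - La))) * sum_m ||c_m - cbar||^2}.
#' Zero iff all content vectors are equal; scales quadratically.
#'
#' @param fs A \linkS4class{FeatureSet} or a plain M x D feature matrix.
#' @param La Appearance length; content is columns La+1..D.
#' @return Nonnegative scalar; 0 (with a warning) when \code{La = D}.
#' @export
contentConsistencyLoss <- function(fs, La = if (is(fs, "FeatureSet")) fs@La
                                   else 0L) {
  F <- .featMatrix(fs)
  D <- ncol(F)
  if (La >= D) {
    warning("content part is empty (La = D); content loss undefined, ",
            "returning 0")
    return(0)
  }
  C <- F[, seq_len(D - La) + La, drop = FALSE]
  cbar <- colMeans(C)
  sum(sweep(C, 2L, cbar)^2) / (nrow(C) * (D - La))
}

#' @noRd
.contentLossGrad <- function(C) {
  cbar <- colMeans(C)
  2 * sweep(C, 2L, cbar) / (nrow(C) * ncol(C))
}

#' Appearance-separation loss
#'
#' Pushes the modality-specific appearance parts away from each other: the
#' mean over all unordered modality pairs of the squared cosine similarity
#' \code{cos^2(a_m, a_n)} (zero vectors contribute cos = 0). Bounded in
#' [0, 1]; 1 when all appearance vectors are collinear, 0 when pairwise
#' orthogonal.
#'
#' @param fs A \linkS4class{FeatureSet} or a plain M x D feature matrix.
#' @param La Appearance length; appearance is columns 1..La.
#' @return Scalar in [0, 1]; 0 (with a warning) when \code{La = 0}.
#' @export
appearanceSeparationLoss <- function(fs, La = if (is(fs, "FeatureSet")) fs@La
                                     else ncol(.featMatrix(fs))) {
  F <- .featMatrix(fs)
  if (La <= 0L) {
    warning("appearance part is empty (La = 0); appearance loss undefined, ",
            "returning 0")
    return(0)
  }
  A <- F[, seq_len(La), drop = FALSE]
  .appearanceLossGrad(A, gradient = FALSE)$loss
}

# Loss and (optionally) gradient of the mean squared pairwise cosine.
#' @noRd
.appearanceLossGrad <- function(A, gradient = TRUE) {
  M <- nrow(A)
  nPairs <- M * (M - 1) / 2
  norms <- unname(sqrt(rowSums(A^2)))
  A <- unname(A)
  loss <- 0
  grad <- if (gradient) matrix(0, M, ncol(A)) else NULL
  for (m in seq_len(M - 1L)) {
    if (norms[m] == 0) next
    for (n in seq.int(m + 1L, M)) {
      if (norms[n] == 0) next
      s <- sum(A[m, ] * A[n, ])
      cs <- s / (norms[m] * norms[n])
      loss <- loss + cs^2
      if (gradient) {
        grad[m, ] <- grad[m, ] +
          2 * cs * (A[n, ] / (norms[m] * norms[n]) - cs * A[m, ] / norms[m]^2)
        grad[n, ] <- grad[n, ] +
          2 * cs * (A[m, ] / (norms[m] * norms[n]) - cs * A[n, ] / norms[n]^2)
      }
    }
  }
  list(loss = loss / nPairs,
       grad = if (gradient) grad / nPairs else NULL)
}

#' Two-class cross-entropy
#'
#' \code{-log p(label)} with probabilities clamped at 1e-12 so the loss is
#' finite for all valid inputs.
#'
#' @param prob Numeric (pScn, pMcn) pair.
#' @param label \code{"SCN"} or \code{"MCN"}.
#' @return Nonnegative scalar.
#' @export
crossEntropy <- function(prob, label) {
  checkLabel(label)
  p <- prob[if (label == "SCN") 1L else 2L]
  -log(max(p, 1e-12))
}

#' Total training loss
#'
#' \code{L = CE(main, label) + lambdaAux * sum_m CE(secondary_m, label) +
#' lambdaContent * L_c + lambdaAppearance * L_app}. Secondary, content and
#' appearance terms are skipped when their inputs are absent (e.g.
#' image-level fusion has no secondary outputs; non-DIS models have no
#' disentanglement constraints).
#'
#' @param main Numeric (pScn, pMcn) main output.
#' @param secondary 7 x 2 matrix of secondary outputs (rows = modalities),
#'   or NULL.
#' @param label \code{"SCN"} or \code{"MCN"}.
#' @param fs A \linkS4class{FeatureSet} (with its La partition), or NULL.
#' @param weights A \code{\link{lossWeights}} list.
#' @return Scalar loss, always \code{>= CE(main, label)}.
#' @export
totalLoss <- function(main, secondary = NULL, label, fs = NULL,
                      weights = lossWeights()) {
  L <- crossEntropy(main, label)
  if (!is.null(secondary) && weights$lambdaAux > 0) {
    for (m in seq_len(nrow(secondary))) {
      L <- L + weights$lambdaAux * crossEntropy(secondary[m, ], label)
    }
  }
  if (!is.null(fs)) {
    D <- ncol(.featMatrix(fs))
    La <- if (is(fs, "FeatureSet")) fs@La else 0L
    if (weights$lambdaContent > 0 && La < D) {
      L <- L + weights$lambdaContent * contentConsistencyLoss(fs, La)
    }
    if (weights$lambdaAppearance > 0 && La > 0L) {
      L <- L + weights$lambdaAppearance * appearanceSeparationLoss(fs, La)
    }
  }
  L
}
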