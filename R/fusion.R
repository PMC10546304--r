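#' Construct a FeatureSet
#'
#' @param features 7 x D numeric matrix of per-modality feature vectors,
#'   rows in canonical modality order.
#' @param La Appearance length in [0, D]: the first \code{La} coordinates
#'   of each vector form the modality-specific appearance part, the rest
#'   the shared content part.
#' @return A \linkS4class{FeatureSet}.
#' @export
featureSet <- function(features, La = 0L) {
  features <- as.matrix(features)
  rownames(features) <- .MODALITIES
  new("FeatureSet", features = features, La = as.integer(La))
}

#' @noRd
.checkFeatureSet <- function(fs) {
  stopifnot(is(fs, "FeatureSet"))
  validObject(fs)
  fs
}

#' Fusion operations over seven per-modality feature vectors
#'
#' \code{fuseSum} and \code{fuseMax} combine the seven vectors elementwise
#' (sum / max), producing a length-D fused feature; both are invariant to
#' modality permutation. \code{fuseCat} concatenates the vectors in
#' canonical modality order (length 7D). \code{fuseDis} is the
#' disentanglement fusion: the modality-specific appearance parts (first
#' \code{La} coordinates) are concatenated in canonical order while the
#' shared content parts are summed, giving length
#' \code{7 * La + (D - La)}. \code{fuseDis} with \code{La = 0} reduces
#' exactly to \code{fuseSum}, and with \code{La = D} to \code{fuseCat}.
#'
#' @param fs A \linkS4class{FeatureSet}.
#' @param La Appearance length for \code{fuseDis}; defaults to the set's
#'   own partition.
#' @return Numeric fused feature vector.
#' @examples
#' fs <- featureSet(matrix(rep(1:7, each = 3), 7, 3, byrow = FALSE), La = 1)
#' fuseDis(fs)   # appearance concat then content sums
#' @name fusion
NULL

#' @rdname fusion
#' @export
fuseSum <- function(fs) {
  fs <- .checkFeatureSet(fs)
  colSums(fs@features)
}

#' @rdname fusion
#' @export
fuseMax <- function(fs) {
  fs <- .checkFeatureSet(fs)
  apply(fs@features, 2L, max)
}

#' @rdname fusion
#' @export
fuseCat <- function(fs) {
  fs <- .checkFeatureSet(fs)
  as.vector(t(fs@features))
}

#' @rdname fusion
#' @export
fuseDis <- function(fs, La = fs@La) {
  fs <- .checkFeatureSet(fs)
  D <- ncol(fs@features)
  La <- as.integer(La)
  if (La < 0L || La > D) {
    stop("La must lie in [0, ", D, "]", call. = FALSE)
  }
  app <- fs@features[, seq_len(La), drop = FALSE]
  con <- fs@features[, seq_len(D - La) + La, drop = FALSE]
  c(as.vector(t(app)), colSums(con))
}

#' Length of a fused feature
#'
#' D for SUM/MAX and image-level fusion, 7D for CAT, and
#' \code{7 * La + (D - La)} for DIS.
#'
#' @param method One of "SUM", "MAX", "CAT", "DIS", "IMG-F".
#' @param D Per-modality feature length.
#' @param La Appearance length (DIS only).
#' @return Integer length.
#' @export
fusedLength <- function(method, D, La = 0L) {
  switch(method,
         "SUM" = , "MAX" = , "IMG-F" = as.integer(D),
         "CAT" = as.integer(7L * D),
         "DIS" = as.integer(7L * La + (D - La)),
         stop("unknown fusion method: ", method, call. = FALSE))
}

# Route the gradient at the fused feature back to the 7 x D feature matrix.
#' @noRd
.unfuse <- function(method, dFused, F, La) {
  D <- ncol(F)
  dF <- matrix(0, 7L, D)
  if (method == "SUM") {
    dF[] <- rep(dFused, each = 7L)
  } else if (method == "MAX") {
    amax <- max.col(t(F), ties.method = "first")
    dF[cbind(amax, seq_len(D))] <- dFused
  } else if (method == "CAT") {
    dF[] <- matrix(dFused, 7L, D, byrow = TRUE)
  } else if (method == "DIS") {
    if (La > 0L) {
      dF[, seq_len(La)] <- matrix(dFused[seq_len(7L * La)], 7L, La,
                                  byrow = TRUE)
    }
    if (La < D) {
      dCon <- dFused[7L * La + seq_len(D - La)]
      dF[, seq_len(D - La) + La] <- rep(dCon, each = 7L)
    }
  } else stop("unknown fusion method: ", method)
  dF
}
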