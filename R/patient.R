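#' Modality majority vote over secondary outputs
#'
#' Each of the seven per-modality secondary outputs votes MCN iff its
#' \code{p_mcn >= 0.5}; the majority of the seven votes wins (with seven
#' voters a tie is impossible). This is the naive result-level "Average
#' Result" fusion.
#'
#' @param secondary Either a 7 x 2 matrix of (pScn, pMcn) rows or a
#'   numeric vector of seven p_mcn values.
#' @return \code{"SCN"} or \code{"MCN"}.
#' @export
modalityMajorityVote <- function(secondary) {
  pMcn <- if (is.matrix(secondary)) secondary[, 2L] else secondary
  if (length(pMcn) != 7L) {
    stop("expected exactly 7 modality outputs, got ", length(pMcn),
         call. = FALSE)
  }
  if (sum(pMcn >= 0.5) > 3L) "MCN" else "SCN"
}

#' Patient-level majority vote over slice probabilities
#'
#' Each slice votes at threshold 0.5 (exactly 0.5 votes MCN); the majority
#' wins. On an exact vote tie the mean \code{p_mcn} against 0.5 decides,
#' and a mean of exactly 0.5 predicts MCN (the malignant-leaning class).
#'
#' @param pMcn Nonempty numeric vector of per-slice MCN probabilities.
#' @return \code{"SCN"} or \code{"MCN"}.
#' @export
patientVote <- function(pMcn) {
  if (length(pMcn) == 0L) stop("no slice scores", call. = FALSE)
  if (any(pMcn < 0 | pMcn > 1)) {
    stop("p_mcn values must lie in [0, 1]", call. = FALSE)
  }
  mcnVotes <- sum(pMcn >= 0.5)
  scnVotes <- length(pMcn) - mcnVotes
  if (mcnVotes > scnVotes) return("MCN")
  if (mcnVotes < scnVotes) return("SCN")
  if (mean(pMcn) >= 0.5) "MCN" else "SCN"
}

#' Summary-feature representation of a patient's slice scores
#'
#' The 9-vector fed to the SVM slice-fusion aggregator: mean, sd, min,
#' max, median, 25th and 75th percentile (linear interpolation), fraction
#' of slices with \code{p_mcn > 0.5}, and \code{log(1 + n_slices)}.
#' Invariant under slice reordering.
#'
#' @param pMcn Nonempty numeric vector of per-slice MCN probabilities.
#' @return Named numeric vector of length 9.
#' @export
buildPatientFeature <- function(pMcn) {
  if (length(pMcn) == 0L) stop("no slice scores", call. = FALSE)
  if (any(pMcn < 0 | pMcn > 1)) {
    stop("p_mcn values must lie in [0, 1]", call. = FALSE)
  }
  s <- if (length(pMcn) > 1L) stats::sd(pMcn) else 0
  q <- stats::quantile(pMcn, c(0.25, 0.5, 0.75), names = FALSE)
  c(mean = mean(pMcn), sd = s, min = min(pMcn), max = max(pMcn),
    median = q[2], q25 = q[1], q75 = q[3], fracMcn = mean(pMcn > 0.5),
    logN = log1p(length(pMcn)))
}

#' Fit the SVM slice-fusion aggregator
#'
#' A max-margin classifier with RBF kernel on standardized patient summary
#' features (\code{\link{buildPatientFeature}}). Standardization
#' parameters are learned from the training patients only, so
#' fitting on one cross-validation fold never sees another fold's
#' patients.
#'
#' @param features Matrix with one row per training patient (9 columns).
#' @param labels Character vector of \code{"SCN"}/\code{"MCN"}, both
#'   classes present.
#' @param cost SVM cost parameter C.
#' @return An aggregator object for \code{\link{svmPatientPredict}}.
#' @export
svmPatientFit <- function(features, labels, cost = 1) {
  features <- as.matrix(features)
  if (nrow(features) < 2L || length(unique(labels)) < 2L) {
    stop("need >= 2 training patients covering both classes", call. = FALSE)
  }
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  y <- factor(labels, levels = .LABELS)
  # constant columns cannot be standardized; exclude them from scaling
  scalable <- apply(features, 2L, function(v) stats::sd(v) > 0)
  fit <- e1071::svm(x = features, y = y, kernel = "radial", cost = cost,
                    scale = scalable, probability = FALSE)
  dv <- attr(stats::predict(fit, features, decision.values = TRUE),
             "decision.values")
  # orient the decision value so larger = more MCN-like
  flip <- identical(colnames(dv), "SCN/MCN")
  structure(list(fit = fit, flip = flip), class = "svmAggregator")
}

#' Predict a patient-level diagnosis from the SVM aggregator
#'
#' @param aggregator Object from \code{\link{svmPatientFit}}.
#' @param features Numeric 9-vector or a matrix of rows.
#' @return data.frame with columns \code{label} and \code{score} (a
#'   continuous MCN-leaning decision value usable for ROC analysis).
#' @export
svmPatientPredict <- function(aggregator, features) {
  stopifnot(inherits(aggregator, "svmAggregator"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  pred <- stats::predict(aggregator$fit, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1L]
  if (aggregator$flip) dv <- -dv
  data.frame(label = as.character(pred), score = unname(dv),
             stringsAsFactors = FALSE)
}
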