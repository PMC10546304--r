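#' Confusion counts with MCN as the positive class
#'
#' @param preds,labels Equal-length character vectors of
#'   \code{"SCN"}/\code{"MCN"}.
#' @return A \linkS4class{ConfusionCounts}: trueMcn (MCN predicted MCN),
#'   falseScn (MCN predicted SCN), trueScn (SCN predicted SCN), falseMcn
#'   (SCN predicted MCN).
#' @export
confusionCounts <- function(preds, labels) {
  if (length(preds) != length(labels)) {
    stop("preds and labels must have equal length", call. = FALSE)
  }
  if (!all(preds %in% .LABELS) || !all(labels %in% .LABELS)) {
    stop("predictions and labels must be SCN or MCN", call. = FALSE)
  }
  new("ConfusionCounts",
      trueMcn = sum(labels == "MCN" & preds == "MCN"),
      falseScn = sum(labels == "MCN" & preds == "SCN"),
      trueScn = sum(labels == "SCN" & preds == "SCN"),
      falseMcn = sum(labels == "SCN" & preds == "MCN"))
}

#' Sensitivity, specificity and accuracy
#'
#' Sensitivity = trueMcn / (trueMcn + falseScn) (accuracy on MCN, the
#' positive class); specificity = trueScn / (trueScn + falseMcn) (accuracy
#' on SCN); accuracy = (trueMcn + trueScn) / all. A metric with a zero
#' denominator is reported as NA with a warning, never a division error.
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return Named numeric (sensitivity, specificity, accuracy).
#' @export
sensSpecAcc <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  nMcn <- counts@trueMcn + counts@falseScn
  nScn <- counts@trueScn + counts@falseMcn
  sens <- if (nMcn > 0L) counts@trueMcn / nMcn else {
    warning("no MCN cases; sensitivity undefined"); NA_real_
  }
  spec <- if (nScn > 0L) counts@trueScn / nScn else {
    warning("no SCN cases; specificity undefined"); NA_real_
  }
  acc <- if (nMcn + nScn > 0L) (counts@trueMcn + counts@trueScn) /
    (nMcn + nScn) else {
      warning("empty sample; accuracy undefined"); NA_real_
    }
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

#' Area under the ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over every observed score, forms the ROC
#' working points, and integrates by the trapezoid rule. Ties contribute
#' half, so the value equals the pairwise Mann-Whitney statistic
#' P(score_pos > score_neg) + 0.5 P(score_pos = score_neg).
#'
#' @param scores Numeric MCN-leaning scores (higher = more MCN-like).
#' @param labels Character \code{"SCN"}/\code{"MCN"}; both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  pos <- labels == "MCN"
  if (!any(pos) || all(pos)) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  P <- sum(pos); N <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # group tied scores into single working points
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Stratified patient-level fold assignment
#'
#' Shuffles patients within each class (seeded) and distributes them so
#' that per-fold class counts differ from perfect proportionality by at
#' most one patient; classes' surplus patients go to the currently
#' smallest folds, keeping total fold sizes within one of each other.
#'
#' @param patients Character vector of unique patient ids.
#' @param labels Class labels, parallel to \code{patients}.
#' @param k Number of folds (>= 2); every class must have >= k patients.
#' @param seed Integer seed.
#' @return A \linkS4class{FoldAssignment} (fold indices 0..k-1).
#' @export
makeFolds <- function(patients, labels, k = 4L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (anyDuplicated(patients)) {
    stop("patient ids must be unique", call. = FALSE)
  }
  if (length(patients) != length(labels)) {
    stop("patients and labels must have equal length", call. = FALSE)
  }
  classes <- intersect(.LABELS, unique(labels))
  if (length(classes) == 0L) classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < k)) {
    stop("every class needs at least k patients", call. = FALSE)
  }
  assign <- integer(length(patients))
  names(assign) <- patients
  foldTotals <- integer(k)
  withSeed(seed, {
    for (cl in classes) {
      ids <- patients[labels == cl]
      ids <- ids[sample.int(length(ids))]
      n <- length(ids)
      base <- n %/% k
      extra <- n %% k
      perFold <- rep(base, k)
      if (extra > 0L) {
        recipients <- order(foldTotals, seq_len(k))[seq_len(extra)]
        perFold[recipients] <- perFold[recipients] + 1L
      }
      f <- rep(seq_len(k) - 1L, times = perFold)
      assign[ids] <- f
      foldTotals <- foldTotals + perFold
    }
  })
  new("FoldAssignment", folds = assign, k = k)
}

#' Aggregate per-fold metrics
#'
#' Mean, sample standard deviation, minimum and maximum of each metric
#' across folds; a metric undefined (NA) in some folds is averaged over
#' the folds where it exists, with a warning counting the exclusions.
#' With a single fold the sd is reported as 0.
#'
#' @param perFold data.frame with a \code{fold} column and one numeric
#'   column per metric.
#' @return A \linkS4class{MetricReport}.
#' @export
aggregateFolds <- function(perFold) {
  stopifnot(is.data.frame(perFold), "fold" %in% names(perFold))
  metrics <- setdiff(names(perFold), "fold")
  rows <- lapply(metrics, function(mn) {
    v <- perFold[[mn]]
    nMiss <- sum(is.na(v))
    if (nMiss > 0L) {
      warning(mn, " undefined in ", nMiss, " fold(s); excluded from mean")
    }
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(data.frame(metric = mn, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_))
    }
    data.frame(metric = mn, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v), max = max(v))
  })
  new("MetricReport", perFold = perFold, summary = do.call(rbind, rows))
}

#' Render a metric report as "mean +/- sd [min, max]" strings
#'
#' Both the dispersion readings (sd and fold range) are printed so either
#' convention is recoverable.
#'
#' @param report A \linkS4class{MetricReport}.
#' @param digits Number of decimal places.
#' @return Named character vector, one entry per metric.
#' @export
formatMetricReport <- function(report, digits = 2L) {
  s <- report@summary
  out <- sprintf(paste0("%.", digits, "f ± %.", digits, "f [%.", digits,
                        "f, %.", digits, "f]"),
                 s$mean, s$sd, s$min, s$max)
  names(out) <- s$metric
  out
}
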