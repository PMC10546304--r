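# Score a list of packs under one model: main p_mcn plus the seven
# secondary p_mcn values per pack.
#' @noRd
.scorePacks <- function(model, packs) {
  n <- length(packs)
  main <- numeric(n)
  sec <- matrix(NA_real_, n, 7L, dimnames = list(NULL, .MODALITIES))
  for (i in seq_len(n)) {
    r <- forwardSlice(packs[[i]], model)
    main[i] <- r$main[["pMcn"]]
    if (!is.null(r$secondary)) sec[i, ] <- r$secondary[, "pMcn"]
  }
  df <- data.frame(
    patient_id = vapply(packs, function(p) p@patientId, ""),
    z_index = vapply(packs, function(p) p@zIndex, 0L),
    label = vapply(packs, function(p) p@label, ""),
    p_mcn = main, stringsAsFactors = FALSE)
  for (m in .MODALITIES) df[[paste0("p_", m)]] <- sec[, m]
  df
}

#' @noRd
.sliceMetricRow <- function(fold, scores, labels) {
  preds <- ifelse(scores >= 0.5, "MCN", "SCN")
  ssa <- sensSpecAcc(confusionCounts(preds, labels))
  data.frame(fold = fold, sensitivity = ssa[["sensitivity"]],
             specificity = ssa[["specificity"]],
             accuracy = ssa[["accuracy"]],
             auc = rocAuc(scores, labels))
}

#' Cross-validated fusion experiment on a slice-pack cohort
#'
#' Runs stratified patient-level k-fold cross-validation: in each fold a
#' fresh model is trained on the training folds' packs and scores the
#' held-out fold's packs. Slice-level metrics are computed for the main
#' (fused) output, for each modality's secondary output (single-modality
#' evaluation), and for the naive "Average Result" modality vote; slice
#' probabilities are then fused into patient-level diagnoses by majority
#' voting or the SVM aggregator (trained, per fold, only on training-fold
#' patients). Metrics are averaged over folds with their fold ranges.
#'
#' @param packs List of labeled \linkS4class{SlicePack} covering the
#'   cohort (all slices of a patient stay in one fold).
#' @param method,backbone,D,La,hidden Model settings
#'   (\code{\link{fusionModel}}).
#' @param k Number of folds.
#' @param seed Master seed; per-fold model/training seeds derive from it.
#' @param trainCfg A \code{\link{trainConfig}} (its seed field is
#'   re-derived per fold).
#' @param patientMethod "svm" or "vote".
#' @param nAug Augmented copies per training pack (0 disables
#'   augmentation).
#' @return List with \code{reports} (MetricReport for \code{fusion},
#'   \code{patient}, \code{ar}, and one per modality), \code{sliceScores}
#'   (out-of-fold per-slice probabilities), \code{patientPredictions},
#'   \code{folds}, per-fold training-loss \code{traces} and a leakage
#'   \code{audit} table.
#' @export
runExperiment <- function(packs, method = "DIS", backbone = "tiny",
                          D = 16L, La = 4L, hidden = 32L, k = 4L,
                          seed = 1L, trainCfg = trainConfig(),
                          patientMethod = c("svm", "vote"), nAug = 0L) {
  patientMethod <- match.arg(patientMethod)
  pids <- vapply(packs, function(p) p@patientId, "")
  labs <- vapply(packs, function(p) p@label, "")
  if (any(is.na(labs))) stop("all packs must be labeled", call. = FALSE)
  patients <- unique(pids)
  plab <- labs[match(patients, pids)]
  fa <- makeFolds(patients, plab, k = k, seed = seed)

  perMod <- stats::setNames(vector("list", 7L), .MODALITIES)
  mainRows <- arRows <- patRows <- list()
  modRows <- lapply(perMod, function(x) list())
  sliceScores <- list()
  patPred <- list()
  audit <- list()
  traces <- list()

  for (f in seq_len(k) - 1L) {
    valPat <- patients[foldOf(fa, patients) == f]
    trainPat <- setdiff(patients, valPat)
    audit[[f + 1L]] <- data.frame(
      fold = f, n_train = length(trainPat), n_val = length(valPat),
      disjoint = length(intersect(trainPat, valPat)) == 0L)
    trainPacks <- packs[pids %in% trainPat]
    valPacks <- packs[pids %in% valPat]
    if (nAug > 0L) {
      trainPacks <- augmentPacks(trainPacks, nAug = nAug,
                                 seed = deriveSeed(seed, 300L + f))
    }
    model <- fusionModel(method = method, backbone = backbone, D = D,
                         La = La, hidden = hidden,
                         seed = deriveSeed(seed, 100L + f))
    cfg <- trainCfg
    cfg$seed <- deriveSeed(seed, 200L + f)
    fit <- trainModel(trainPacks, model, cfg)
    model <- fit$model
    traces[[f + 1L]] <- fit$trace

    val <- .scorePacks(model, valPacks)
    val$fold <- f
    sliceScores[[f + 1L]] <- val

    mainRows[[f + 1L]] <- .sliceMetricRow(f, val$p_mcn, val$label)
    if (method != "IMG-F") {
      for (m in .MODALITIES) {
        modRows[[m]][[f + 1L]] <-
          .sliceMetricRow(f, val[[paste0("p_", m)]], val$label)
      }
      secCols <- paste0("p_", .MODALITIES)
      arPred <- apply(as.matrix(val[secCols]), 1L, modalityMajorityVote)
      arScore <- rowMeans(as.matrix(val[secCols]) >= 0.5)
      ssa <- sensSpecAcc(confusionCounts(arPred, val$label))
      arRows[[f + 1L]] <- data.frame(
        fold = f, sensitivity = ssa[["sensitivity"]],
        specificity = ssa[["specificity"]], accuracy = ssa[["accuracy"]],
        auc = rocAuc(arScore, val$label))
    }

    valByPat <- split(val$p_mcn, val$patient_id)
    valLabels <- plab[match(names(valByPat), patients)]
    if (patientMethod == "vote") {
      pred <- vapply(valByPat, patientVote, "")
      score <- vapply(valByPat, mean, 0)
    } else {
      tr <- .scorePacks(model, trainPacks)
      trByPat <- split(tr$p_mcn, tr$patient_id)
      trFeat <- t(vapply(trByPat, buildPatientFeature, numeric(9L)))
      trLab <- plab[match(names(trByPat), patients)]
      agg <- svmPatientFit(trFeat, trLab)
      valFeat <- t(vapply(valByPat, buildPatientFeature, numeric(9L)))
      pr <- svmPatientPredict(agg, valFeat)
      pred <- pr$label
      score <- pr$score
    }
    ssa <- sensSpecAcc(confusionCounts(pred, valLabels))
    patRows[[f + 1L]] <- data.frame(
      fold = f, sensitivity = ssa[["sensitivity"]],
      specificity = ssa[["specificity"]], accuracy = ssa[["accuracy"]],
      auc = rocAuc(score, valLabels))
    patPred[[f + 1L]] <- data.frame(
      fold = f, patient_id = names(valByPat), label = valLabels,
      pred = pred, score = unname(score), stringsAsFactors = FALSE)
  }

  reports <- list(fusion = aggregateFolds(do.call(rbind, mainRows)),
                  patient = aggregateFolds(do.call(rbind, patRows)))
  if (method != "IMG-F") {
    reports$ar <- aggregateFolds(do.call(rbind, arRows))
    for (m in .MODALITIES) {
      reports[[m]] <- aggregateFolds(do.call(rbind, modRows[[m]]))
    }
  }
  list(reports = reports,
       sliceScores = do.call(rbind, sliceScores),
       patientPredictions = do.call(rbind, patPred),
       folds = fa, audit = do.call(rbind, audit), traces = traces,
       settings = list(method = method, backbone = backbone, D = D, La = La,
                       k = k, seed = seed, patientMethod = patientMethod,
                       nAug = nAug))
}

#' Tabulate an experiment's aggregated results
#'
#' One row per evaluated output (each modality, the Average-Result vote,
#' the fused model, the patient-level aggregation) per fold, plus
#' aggregate rows (fold = "mean"/"sd"/"min"/"max").
#'
#' @param experiment Result of \code{\link{runExperiment}}.
#' @return data.frame with columns method, fold, sensitivity, specificity,
#'   accuracy, auc.
#' @export
experimentResultsTable <- function(experiment) {
  out <- list()
  for (nm in names(experiment$reports)) {
    rep <- experiment$reports[[nm]]
    pf <- rep@perFold
    pf <- data.frame(method = nm, fold = as.character(pf$fold),
                     pf[setdiff(names(pf), "fold")],
                     stringsAsFactors = FALSE)
    s <- rep@summary
    for (stat in c("mean", "sd", "min", "max")) {
      row <- data.frame(method = nm, fold = stat, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(s))) row[[s$metric[i]]] <- s[[stat]][i]
      pf <- rbind(pf, row)
    }
    out[[nm]] <- pf
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
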