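#' @rdname ModalityVolume-class
#' @export
setMethod("voxels", "ModalityVolume", function(x) x@voxels)

#' @rdname ModalityVolume-class
#' @export
setMethod("spacingMm", "ModalityVolume", function(x) x@spacingMm)

#' @rdname ModalityVolume-class
#' @export
setMethod("modality", "ModalityVolume", function(x) x@modality)

#' @rdname PatientSeries-class
#' @export
setMethod("patientId", "PatientSeries", function(x) x@patientId)

#' @rdname PatientSeries-class
#' @export
setMethod("seriesLabel", "PatientSeries", function(x) x@label)

#' @rdname PatientSeries-class
#' @export
setMethod("modalityVolumes", "PatientSeries", function(x) x@volumes)

#' @rdname PatientSeries-class
#' @export
setMethod("lesionCenters", "PatientSeries", function(x) x@centers)

#' @rdname FeatureSet-class
#' @export
setMethod("features", "FeatureSet", function(x) x@features)

#' @rdname FeatureSet-class
#' @export
setMethod("appearancePart", "FeatureSet", function(x) {
  x@features[, seq_len(x@La), drop = FALSE]
})

#' @rdname FeatureSet-class
#' @export
setMethod("contentPart", "FeatureSet", function(x) {
  D <- ncol(x@features)
  x@features[, seq_len(D - x@La) + x@La, drop = FALSE]
})

#' @rdname FoldAssignment-class
#' @param patient Character vector of patient ids.
#' @export
setMethod("foldOf", "FoldAssignment", function(x, patient) {
  if (!all(patient %in% names(x@folds))) {
    stop("unknown patient id(s): ",
         paste(setdiff(patient, names(x@folds)), collapse = ", "),
         call. = FALSE)
  }
  x@folds[patient]
})

setMethod("show", "ModalityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ModalityVolume %s: %d x %d x %d voxels, spacing %s mm\n",
              object@modality, d[1], d[2], d[3],
              paste(signif(object@spacingMm, 4), collapse = " x ")))
})

setMethod("show", "PatientSeries", function(object) {
  d <- dim(object@volumes[[1]]@voxels)
  cat(sprintf(
    "PatientSeries %s (label: %s), 7 modalities, reference grid %d x %d x %d\n",
    object@patientId, ifelse(is.na(object@label), "unknown", object@label),
    d[1], d[2], d[3]))
})

setMethod("show", "SlicePack", function(object) {
  d <- dim(object@slices)
  cat(sprintf("SlicePack %s z=%d (label: %s), 7 x %d x %d slices\n",
              object@patientId, object@zIndex,
              ifelse(is.na(object@label), "unknown", object@label),
              d[1], d[2]))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: 7 modalities x D=%d (appearance L_a=%d)\n",
              ncol(object@features), object@La))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf(
    "ConfusionCounts (MCN positive): TM=%d FS=%d TS=%d FM=%d\n",
    object@trueMcn, object@falseScn, object@trueScn, object@falseMcn))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport over", nrow(object@perFold), "fold(s)\n")
  s <- object@summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f +/- %.3f [%.3f, %.3f]\n", s$metric[i],
                s$mean[i], s$sd[i], s$min[i], s$max[i]))
  }
})

setMethod("show", "FusionModel", function(object) {
  cat(sprintf("FusionModel: method=%s backbone=%s D=%d L_a=%d hidden=%d\n",
              object@method, object@backbone, object@D, object@La,
              object@hidden))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d patients in %d folds (sizes: %s)\n",
              length(object@folds), object@k,
              paste(tabulate(object@folds + 1L, object@k), collapse = ", ")))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %s, cysts=%d, nodules=%d, scar=%s, center=(%s)\n",
    object@label, object@nCysts, object@nNodules, object@scarPresent,
    paste(object@lesionCenter, collapse = ", ")))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: grid %s, scarProb=%.2f, noiseSd=%.1f, misalignmentSd=%.1f, seed=%d\n",
    paste(object@gridDims, collapse = "x"), object@scarProb, object@noiseSd,
    object@misalignmentSd, object@seed))
})
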