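#' @import methods
NULL

#' ModalityVolume: one 3D MRI volume
#'
#' A single-channel 3D scalar volume with voxel spacing metadata and a
#' modality tag. Axis order is (x, y, z); axial slices are indexed by z.
#'
#' @slot voxels 3D numeric array, all values finite.
#' @slot spacingMm Positive numeric triple, voxel spacing in millimetres.
#' @slot modality One of the seven canonical modality names
#'   (\code{\link{canonicalModalities}}).
#' @export
setClass("ModalityVolume",
  representation(voxels = "array", spacingMm = "numeric",
                 modality = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (!all(is.finite(object@voxels)))
      msg <- c(msg, "voxels must all be finite")
    if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
        any(object@spacingMm <= 0))
      msg <- c(msg, "spacingMm must be a positive triple")
    if (length(object@modality) != 1L ||
        !(object@modality %in% .MODALITIES))
      msg <- c(msg, paste0("modality must be one of ",
                           paste(.MODALITIES, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' PatientSeries: one patient's seven-modality MRI study
#'
#' Holds exactly one \linkS4class{ModalityVolume} per canonical modality,
#' a per-modality lesion-center coordinate (0-based voxel indices; the
#' T1post entry is the reference), and the pathology label when known.
#'
#' @slot patientId Character scalar.
#' @slot label \code{"SCN"}, \code{"MCN"}, or \code{NA} (inference mode).
#' @slot volumes Named list of seven ModalityVolume objects in canonical
#'   order.
#' @slot centers 7 x 3 numeric matrix of 0-based lesion-center voxel
#'   coordinates, one row per modality.
#' @export
setClass("PatientSeries",
  representation(patientId = "character", label = "character",
                 volumes = "list", centers = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@patientId) != 1L || !nzchar(object@patientId))
      msg <- c(msg, "patientId must be a nonempty string")
    if (length(object@label) != 1L ||
        !(is.na(object@label) || object@label %in% .LABELS))
      msg <- c(msg, "label must be SCN, MCN or NA")
    if (length(object@volumes) != 7L ||
        !identical(names(object@volumes), .MODALITIES))
      msg <- c(msg, paste0("volumes must be a named list of the 7 canonical ",
                           "modalities in order; missing: ",
                           paste(setdiff(.MODALITIES, names(object@volumes)),
                                 collapse = ", ")))
    else {
      ok <- vapply(object@volumes, function(v) is(v, "ModalityVolume"), TRUE)
      if (!all(ok)) msg <- c(msg, "all volumes must be ModalityVolume objects")
      else {
        tags <- vapply(object@volumes, function(v) v@modality, "")
        if (!identical(unname(tags), .MODALITIES))
          msg <- c(msg, "volume modality tags must match their list names")
      }
    }
    if (!identical(dim(object@centers), c(7L, 3L)))
      msg <- c(msg, "centers must be a 7 x 3 matrix")
    else if (length(object@volumes) == 7L &&
             all(vapply(object@volumes, function(v) is(v, "ModalityVolume"),
                        TRUE))) {
      for (m in seq_len(7L)) {
        d <- dim(object@volumes[[m]]@voxels)
        ctr <- object@centers[m, ]
        if (any(!is.finite(ctr)) || any(ctr < 0) || any(ctr > d - 1)) {
          msg <- c(msg, sprintf("lesion center of %s outside its volume",
                                .MODALITIES[m]))
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' SlicePack: seven paired axial slices at one position
#'
#' The unit sample seen by the network: seven aligned, normalized 80 x 80
#' axial slices (one per modality) cut from a cropped series at the same
#' z position.
#'
#' @slot patientId Character scalar.
#' @slot zIndex Integer, 0-based axial position within the 80-voxel crop.
#' @slot slices 80 x 80 x 7 numeric array, values in [-1, 1], third axis in
#'   canonical modality order.
#' @slot label \code{"SCN"}, \code{"MCN"} or \code{NA}.
#' @export
setClass("SlicePack",
  representation(patientId = "character", zIndex = "integer",
                 slices = "array", label = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@slices)
    if (length(d) != 3L || d[3] != 7L || d[1] != d[2])
      msg <- c(msg, "slices must be an N x N x 7 array")
    if (any(!is.finite(object@slices)) ||
        any(object@slices < -1 - 1e-9) || any(object@slices > 1 + 1e-9))
      msg <- c(msg, "slice values must lie in [-1, 1]")
    if (length(object@label) != 1L ||
        !(is.na(object@label) || object@label %in% .LABELS))
      msg <- c(msg, "label must be SCN, MCN or NA")
    if (length(msg)) msg else TRUE
  })

#' FeatureSet: per-modality feature vectors with a DIS partition
#'
#' A 7 x D matrix of per-modality feature vectors (rows in canonical
#' modality order) together with the appearance length L_a that splits each
#' vector into a modality-specific appearance part (first \code{La}
#' coordinates) and a shared content part (the remainder).
#'
#' @slot features 7 x D numeric matrix, rownames the canonical modalities.
#' @slot La Integer in [0, D].
#' @export
setClass("FeatureSet",
  representation(features = "matrix", La = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@features) != 7L)
      msg <- c(msg, "features must have 7 rows (one per modality)")
    if (!all(is.finite(object@features)))
      msg <- c(msg, "features must be finite")
    D <- ncol(object@features)
    if (length(object@La) != 1L || object@La < 0L || object@La > D)
      msg <- c(msg, "La must lie in [0, D]")
    if (length(msg)) msg else TRUE
  })

#' ConfusionCounts: two-class confusion table with MCN positive
#'
#' @slot trueMcn,falseScn,trueScn,falseMcn Nonnegative integer counts.
#'   \code{falseScn} counts MCN cases predicted SCN; \code{falseMcn} counts
#'   SCN cases predicted MCN.
#' @export
setClass("ConfusionCounts",
  representation(trueMcn = "integer", falseScn = "integer",
                 trueScn = "integer", falseMcn = "integer"),
  validity = function(object) {
    v <- c(object@trueMcn, object@falseScn, object@trueScn, object@falseMcn)
    if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
      "all four counts must be nonnegative integers" else TRUE
  })

#' FoldAssignment: patient-level stratified fold map
#'
#' @slot folds Named integer vector mapping patient_id to fold index in
#'   0..(k-1).
#' @slot k Integer number of folds.
#' @export
setClass("FoldAssignment",
  representation(folds = "integer", k = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@folds)) || anyDuplicated(names(object@folds)))
      msg <- c(msg, "folds must be named by unique patient ids")
    if (any(object@folds < 0L) || any(object@folds >= object@k))
      msg <- c(msg, "fold indices must lie in 0..(k-1)")
    if (length(msg)) msg else TRUE
  })

#' MetricReport: per-fold metrics with cross-fold aggregation
#'
#' @slot perFold data.frame with a \code{fold} column and one column per
#'   metric (sensitivity, specificity, accuracy, auc); NA marks a metric
#'   undefined in that fold.
#' @slot summary data.frame with columns metric, mean, sd, min, max.
#' @export
setClass("MetricReport",
  representation(perFold = "data.frame", summary = "data.frame"))

#' PhantomConfig: parameters of the synthetic lesion phantom generator
#'
#' See \code{\link{phantomConfig}} for field semantics and defaults.
#' @slot gridDims Integer triple, voxel grid size.
#' @slot spacingT1Range,spacingT2Range 2 x 3 matrices, (min, max) spacing in
#'   mm for the six T1 phases and for T2.
#' @slot scarProb Probability that an SCN phantom carries a central scar.
#' @slot cystCountRange Integer range of SCN cyst counts.
#' @slot cystRadiusRange SCN cyst semi-axis range, mm.
#' @slot mcnRadiusRange MCN dominant-cyst semi-axis range, mm.
#' @slot wallThicknessRange Integer range of MCN wall thickness, voxels.
#' @slot noduleCountRange Integer range of MCN wall-nodule counts.
#' @slot noduleRadiusRange MCN nodule radius range, mm.
#' @slot enhancementScn,enhancementMcn Length-7 additive wall/nodule/septum
#'   enhancement per modality (canonical order).
#' @slot noiseSd Gaussian noise SD, raw intensity units.
#' @slot misalignmentSd SD (voxels) of the per-modality rigid shift; 0 = off.
#' @slot classGeometry If TRUE (default) lesion geometry is class-typical;
#'   if FALSE both classes share the same geometry distribution so only
#'   enhancement differs (planted-signal studies).
#' @slot seed Integer RNG seed.
#' @export
setClass("PhantomConfig",
  representation(gridDims = "integer", spacingT1Range = "matrix",
                 spacingT2Range = "matrix", scarProb = "numeric",
                 cystCountRange = "integer", cystRadiusRange = "numeric",
                 mcnRadiusRange = "numeric", wallThicknessRange = "integer",
                 noduleCountRange = "integer", noduleRadiusRange = "numeric",
                 enhancementScn = "numeric", enhancementMcn = "numeric",
                 noiseSd = "numeric", misalignmentSd = "numeric",
                 classGeometry = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridDims) != 3L || any(object@gridDims < 1L))
      msg <- c(msg, "gridDims must be a positive integer triple")
    for (nm in c("spacingT1Range", "spacingT2Range")) {
      r <- slot(object, nm)
      if (!identical(dim(r), c(2L, 3L)) || any(r <= 0) || any(r[1, ] > r[2, ]))
        msg <- c(msg, paste(nm, "must be a 2 x 3 matrix of positive mins/maxs"))
    }
    if (object@scarProb < 0 || object@scarProb > 1)
      msg <- c(msg, "scarProb must lie in [0, 1]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
    if (object@misalignmentSd < 0)
      msg <- c(msg, "misalignmentSd must be nonnegative")
    if (length(object@enhancementScn) != 7L ||
        length(object@enhancementMcn) != 7L)
      msg <- c(msg, "enhancement vectors must have length 7")
    # the crop stage cuts an 80 mm box; the grid must cover it at the
    # smallest spacing the config can draw (T1 geometry is the reference)
    if (!length(msg)) {
      minExtent <- object@gridDims * slot(object, "spacingT1Range")[1, ]
      if (any(minExtent < 80))
        msg <- c(msg, paste0("grid too small: extent ",
                             paste(round(minExtent, 1), collapse = "x"),
                             " mm cannot contain an 80 mm crop"))
    }
    if (length(msg)) msg else TRUE
  })

#' PhantomTruth: analytic ground truth of one phantom
#'
#' @slot label \code{"SCN"} or \code{"MCN"}.
#' @slot scarPresent Logical; central scar component present.
#' @slot nCysts,nNodules Integer counts.
#' @slot lesionCenter 0-based voxel triple.
#' @slot shifts 7 x 3 matrix of per-modality rigid shifts (voxels).
#' @slot roi Named list of linear voxel indices (pre-shift) for the fluid,
#'   wall, septum, nodule and scar compartments.
#' @export
setClass("PhantomTruth",
  representation(label = "character", scarPresent = "logical",
                 nCysts = "integer", nNodules = "integer",
                 lesionCenter = "numeric", shifts = "matrix", roi = "list"),
  validity = function(object) {
    msg <- character()
    if (!(object@label %in% .LABELS)) msg <- c(msg, "label must be SCN or MCN")
    if (object@nCysts < 1L) msg <- c(msg, "nCysts must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' FusionModel: the multi-branch fusion network
#'
#' Seven per-modality convolutional backbones (or one 7-channel backbone for
#' image-level fusion), a fusion block (MAX, SUM, CAT or DIS), a two-layer
#' fully-connected main classifier, and per-modality secondary classifier
#' heads.
#'
#' @slot method One of \code{"SUM"}, \code{"MAX"}, \code{"CAT"},
#'   \code{"DIS"}, \code{"IMG-F"}.
#' @slot backbone \code{"tiny"} or \code{"alexnet-conv"}.
#' @slot D Integer feature length per modality.
#' @slot La Integer appearance length (DIS only; 0 otherwise).
#' @slot hidden Integer width of the classifier hidden layer.
#' @slot weights List of weight tensors (backbones, main head, secondary
#'   heads).
#' @slot config List of architecture details.
#' @slot seed Integer initialization seed.
#' @export
setClass("FusionModel",
  representation(method = "character", backbone = "character",
                 D = "integer", La = "integer", hidden = "integer",
                 weights = "list", config = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@method %in% c("SUM", "MAX", "CAT", "DIS", "IMG-F")))
      msg <- c(msg, "method must be one of SUM, MAX, CAT, DIS, IMG-F")
    if (!(object@backbone %in% c("tiny", "alexnet-conv")))
      msg <- c(msg, "backbone must be 'tiny' or 'alexnet-conv'")
    if (object@La < 0L || object@La > object@D)
      msg <- c(msg, "La must lie in [0, D]")
    if (length(msg)) msg else TRUE
  })
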