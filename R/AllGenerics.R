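#' @rdname ModalityVolume-class
#' @param object,x An object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname ModalityVolume-class
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname ModalityVolume-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname PatientSeries-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname PatientSeries-class
#' @export
setGeneric("seriesLabel", function(x) standardGeneric("seriesLabel"))

#' @rdname PatientSeries-class
#' @export
setGeneric("modalityVolumes", function(x) standardGeneric("modalityVolumes"))

#' @rdname PatientSeries-class
#' @export
setGeneric("lesionCenters", function(x) standardGeneric("lesionCenters"))

#' @rdname FeatureSet-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname FeatureSet-class
#' @export
setGeneric("appearancePart", function(x) standardGeneric("appearancePart"))

#' @rdname FeatureSet-class
#' @export
setGeneric("contentPart", function(x) standardGeneric("contentPart"))

#' @rdname FoldAssignment-class
#' @export
setGeneric("foldOf", function(x, patient) standardGeneric("foldOf"))
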