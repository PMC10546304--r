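#' Read one modality volume from a NIfTI file
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param modality Canonical modality name to tag the volume with.
#' @return A \linkS4class{ModalityVolume}; spacing is taken from the NIfTI
#'   header (pixdim).
#' @export
readVolume <- function(path, modality) {
  checkModality(modality)
  if (!file.exists(path)) {
    stop("volume file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    dim(arr) <- dim(arr)[1:3]
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume in ", path, ", got dims ",
         paste(dim(arr), collapse = "x"), call. = FALSE)
  }
  if (!all(is.finite(arr))) {
    stop("non-finite voxel values in ", path, call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  new("ModalityVolume", voxels = arr, spacingMm = as.numeric(sp),
      modality = modality)
}

#' Write one modality volume to a NIfTI file
#'
#' @param vol A \linkS4class{ModalityVolume}.
#' @param path Output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ModalityVolume"))
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacingMm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom cohort to disk
#'
#' Writes one NIfTI file per modality, a per-patient ground-truth JSON
#' (label, scar, counts, center, per-modality shifts), and a cohort
#' manifest CSV with one row per (patient, modality) carrying that
#' modality's lesion-center voxel coordinates (header:
#' patient_id,label,modality,path,center_x,center_y,center_z).
#'
#' @param cohort A list of \code{list(series=, truth=)} pairs as returned
#'   by \code{\link{generateCohort}}.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
writePhantomCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in cohort) {
    series <- p$series; truth <- p$truth
    pid <- series@patientId
    for (m in seq_len(7L)) {
      mod <- .MODALITIES[m]
      f <- file.path(dir, sprintf("%s_%s.nii.gz", pid, mod))
      writeVolume(series@volumes[[mod]], f)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, label = series@label, modality = mod, path = f,
        center_x = series@centers[m, 1], center_y = series@centers[m, 2],
        center_z = series@centers[m, 3], stringsAsFactors = FALSE)
    }
    tj <- list(patient_id = pid, label = truth@label,
               scar_present = truth@scarPresent, n_cysts = truth@nCysts,
               n_nodules = truth@nNodules,
               lesion_center_vox = as.numeric(truth@lesionCenter),
               per_modality_shift_vox = unname(
                 split(truth@shifts, row(truth@shifts))))
    jsonlite::write_json(tj, file.path(dir, sprintf("%s_truth.json", pid)),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Load a cohort from a manifest CSV
#'
#' Reads one \linkS4class{PatientSeries} per patient and enforces the
#' seven-modality invariant: every patient must have exactly one row per
#' canonical modality and patient ids must be unique.
#'
#' @param manifestCsv Path to a manifest CSV with header
#'   patient_id,label,modality,path,center_x,center_y,center_z.
#' @return List of \linkS4class{PatientSeries}, in first-appearance order.
#' @export
loadCohort <- function(manifestCsv) {
  if (!file.exists(manifestCsv)) {
    stop("manifest not found: ", manifestCsv, call. = FALSE)
  }
  man <- utils::read.csv(manifestCsv, stringsAsFactors = FALSE)
  need <- c("patient_id", "label", "modality", "path",
            "center_x", "center_y", "center_z")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  ids <- unique(man$patient_id)
  if (any(table(man$patient_id, man$modality) > 1L)) {
    stop("duplicate patient_id/modality rows in manifest", call. = FALSE)
  }
  out <- vector("list", length(ids))
  names(out) <- ids
  for (pid in ids) {
    sub <- man[man$patient_id == pid, ]
    missing <- setdiff(.MODALITIES, sub$modality)
    if (length(missing) || nrow(sub) != 7L) {
      stop("patient ", pid, " must have exactly the 7 canonical modalities; ",
           "missing: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    sub <- sub[match(.MODALITIES, sub$modality), ]
    lab <- unique(sub$label)
    if (length(lab) != 1L) {
      stop("patient ", pid, " has inconsistent labels", call. = FALSE)
    }
    vols <- vector("list", 7L)
    names(vols) <- .MODALITIES
    for (m in seq_len(7L)) {
      vols[[m]] <- readVolume(sub$path[m], .MODALITIES[m])
    }
    centers <- as.matrix(sub[, c("center_x", "center_y", "center_z")])
    storage.mode(centers) <- "double"
    dimnames(centers) <- list(.MODALITIES, NULL)
    out[[pid]] <- new("PatientSeries", patientId = pid,
                      label = if (is.na(lab) || lab == "") NA_character_
                              else lab,
                      volumes = vols, centers = centers)
  }
  out
}
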