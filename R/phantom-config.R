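#' Configure the synthetic seven-modality lesion phantom generator
#'
#' The phantom generator builds one shared lesion geometry (the "content")
#' per patient and renders it under seven modality-specific intensity maps
#' (the "appearance"), emulating the imaging signature that separates the
#' two cyst subtypes: serous lesions are multicystic clusters with thin
#' (1-voxel) walls, a lobulated contour and a central scar in a
#' configurable fraction of cases; mucinous lesions are solitary with a
#' thick uneven wall, mural nodules and internal septations whose intensity
#' ramps up strongly on the delayed contrast phases. Cyst fluid is dark on
#' T1 and bright on T2.
#'
#' @param gridDims Integer triple, voxel grid per modality. The default is
#'   the smallest grid whose physical extent still contains the 80 mm crop
#'   box at the minimum T1 spacing.
#' @param spacingT1Range,spacingT2Range 2 x 3 matrices giving (min, max)
#'   spacing in mm from which each patient's T1-phase and T2 spacings are
#'   drawn uniformly. Defaults span the clinical acquisition ranges
#'   (T1 in-plane 0.78-1.04 mm, axial 2.50-2.59 mm; T2 in-plane
#'   0.625-0.88 mm, axial 4.80-8.40 mm).
#' @param scarProb Probability that an SCN phantom carries a central scar;
#'   default 0.30, the fraction reported for serous lesions.
#' @param cystCountRange SCN cyst count range (>= 2: multicystic).
#' @param cystRadiusRange SCN cyst semi-axis range in mm.
#' @param mcnRadiusRange MCN dominant-cyst semi-axis range in mm.
#' @param wallThicknessRange MCN wall thickness range in voxels (2-4); SCN
#'   walls are always 1 voxel.
#' @param noduleCountRange MCN mural nodule count range (1-3).
#' @param noduleRadiusRange MCN nodule radius range in mm.
#' @param enhancementScn,enhancementMcn Length-7 numeric vectors (canonical
#'   modality order): additive wall/nodule/septum enhancement per modality
#'   in raw intensity units. Defaults ramp linearly over the six contrast
#'   phases with a steeper slope for MCN (delayed-phase enhancement) and no
#'   contrast effect on T2.
#' @param noiseSd Gaussian noise SD in raw intensity units.
#' @param misalignmentSd SD (voxels) of a rigid integer translation applied
#'   independently per modality; default 0 (perfect co-registration).
#' @param classGeometry If TRUE (default), lesion geometry follows the
#'   class-typical morphology above. If FALSE both classes draw from the
#'   same (solitary-cyst) geometry distribution so that only the
#'   enhancement vectors can separate the classes - used for
#'   planted-signal experiments.
#' @param seed Integer seed; phantoms are fully determined by (label,
#'   config) including this seed.
#' @return A validated \linkS4class{PhantomConfig}.
#' @seealso \code{\link{generatePhantom}}, \code{\link{generateCohort}}
#' @export
phantomConfig <- function(gridDims = c(104L, 104L, 34L),
                          spacingT1Range = rbind(c(0.78, 0.78, 2.50),
                                                 c(1.04, 1.04, 2.59)),
                          spacingT2Range = rbind(c(0.625, 0.625, 4.80),
                                                 c(0.88, 0.88, 8.40)),
                          scarProb = 0.30,
                          cystCountRange = c(2L, 6L),
                          cystRadiusRange = c(4, 9),
                          mcnRadiusRange = c(12, 18),
                          wallThicknessRange = c(2L, 4L),
                          noduleCountRange = c(1L, 3L),
                          noduleRadiusRange = c(2, 4),
                          enhancementScn = 40 * .PHASE_FRAC,
                          enhancementMcn = 100 * .PHASE_FRAC,
                          noiseSd = 5,
                          misalignmentSd = 0,
                          classGeometry = TRUE,
                          seed = 1L) {
  new("PhantomConfig",
      gridDims = as.integer(gridDims),
      spacingT1Range = matrix(as.numeric(spacingT1Range), 2L, 3L),
      spacingT2Range = matrix(as.numeric(spacingT2Range), 2L, 3L),
      scarProb = as.numeric(scarProb),
      cystCountRange = as.integer(cystCountRange),
      cystRadiusRange = as.numeric(cystRadiusRange),
      mcnRadiusRange = as.numeric(mcnRadiusRange),
      wallThicknessRange = as.integer(wallThicknessRange),
      noduleCountRange = as.integer(noduleCountRange),
      noduleRadiusRange = as.numeric(noduleRadiusRange),
      enhancementScn = as.numeric(enhancementScn),
      enhancementMcn = as.numeric(enhancementMcn),
      noiseSd = as.numeric(noiseSd),
      misalignmentSd = as.numeric(misalignmentSd),
      classGeometry = isTRUE(classGeometry),
      seed = as.integer(seed))
}
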