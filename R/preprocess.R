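# 1D linear-interpolation matrix taking a grid of nIn voxels at the given
# spacing (mm) to a 1 mm grid of roundHalfUp(nIn * spacing) voxels; voxel
# centers sit at (i-1)*spacing, borders are clamped.
#' @noRd
.resampleMatrix <- function(nIn, spacing) {
  nOut <- as.integer(roundHalfUp(nIn * spacing))
  t <- (seq_len(nOut) - 1) / spacing + 1
  t <- pmin(pmax(t, 1), nIn)
  i0 <- pmin(floor(t), nIn - 1L)
  if (nIn == 1L) i0 <- rep(1, nOut)
  w <- t - i0
  W <- matrix(0, nOut, nIn)
  W[cbind(seq_len(nOut), i0)] <- 1 - w
  if (nIn > 1L) W[cbind(seq_len(nOut), i0 + 1L)] <-
    W[cbind(seq_len(nOut), i0 + 1L)] + w
  W
}

#' Resample a volume to isotropic 1 mm spacing
#'
#' Trilinear resampling onto a 1 x 1 x 1 mm grid. Output dimensions are
#' \code{roundHalfUp(dims * spacing)} per axis (half rounds away from
#' zero, so a .5 product always rounds up).
#'
#' @param vol A \linkS4class{ModalityVolume} with positive spacing.
#' @return A \linkS4class{ModalityVolume} with spacing (1, 1, 1).
#' @examples
#' v <- new("ModalityVolume", voxels = array(0, c(10, 10, 4)),
#'          spacingMm = c(0.78, 0.78, 2.59), modality = "T1pre")
#' dim(voxels(resampleIsotropic(v)))   # 8 x 8 x 10
#' @export
resampleIsotropic <- function(vol) {
  stopifnot(is(vol, "ModalityVolume"))
  sp <- vol@spacingMm
  if (any(sp <= 0)) stop("spacing must be positive", call. = FALSE)
  v <- vol@voxels
  d <- dim(v)
  if (all(abs(sp - 1) < 1e-12)) {
    return(new("ModalityVolume", voxels = v, spacingMm = c(1, 1, 1),
               modality = vol@modality))
  }
  Wx <- .resampleMatrix(d[1], sp[1])
  Wy <- .resampleMatrix(d[2], sp[2])
  Wz <- .resampleMatrix(d[3], sp[3])
  ox <- nrow(Wx); oy <- nrow(Wy); oz <- nrow(Wz)
  # separable trilinear interpolation: one matrix product per axis
  a <- array(Wx %*% matrix(v, d[1], d[2] * d[3]), c(ox, d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- array(Wy %*% matrix(a, d[2], ox * d[3]), c(oy, ox, d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- array(matrix(a, ox * oy, d[3]) %*% t(Wz), c(ox, oy, oz))
  new("ModalityVolume", voxels = a, spacingMm = c(1, 1, 1),
      modality = vol@modality)
}

#' Default intensity window of a volume
#'
#' Robust percentile window (0.5th / 99.5th percentile of the nonzero
#' voxels), used when no explicit per-modality window is configured.
#'
#' @param vol A \linkS4class{ModalityVolume}.
#' @return Numeric (lo, hi).
#' @export
defaultWindow <- function(vol) {
  v <- vol@voxels
  v <- v[v != 0]
  if (length(v) == 0L) v <- as.vector(vol@voxels)
  w <- unname(stats::quantile(v, c(0.005, 0.995), names = FALSE))
  if (w[1] >= w[2]) w <- c(min(vol@voxels), min(vol@voxels) + 1)
  w
}

#' Window and normalize a volume into [-1, 1]
#'
#' Truncates intensities to a per-modality window (lo, hi) and maps the
#' window linearly onto [-1, 1]:
#' \code{v' = 2 * (clip(v, lo, hi) - lo) / (hi - lo) - 1}.
#'
#' @param vol A \linkS4class{ModalityVolume}.
#' @param window Either a numeric (lo, hi), a named list mapping modality
#'   names to (lo, hi) pairs, or NULL to use \code{\link{defaultWindow}}.
#' @return A \linkS4class{ModalityVolume} with all values in [-1, 1].
#' @export
windowNormalize <- function(vol, window = NULL) {
  stopifnot(is(vol, "ModalityVolume"))
  if (is.list(window)) window <- window[[vol@modality]]
  if (is.null(window)) window <- defaultWindow(vol)
  if (length(window) != 2L || !all(is.finite(window))) {
    stop("window must be a finite (lo, hi) pair", call. = FALSE)
  }
  if (window[1] >= window[2]) {
    stop("window lo must be < hi, got (", window[1], ", ", window[2], ")",
         call. = FALSE)
  }
  v <- pmin(pmax(vol@voxels, window[1]), window[2])
  v <- 2 * (v - window[1]) / (window[2] - window[1]) - 1
  dim(v) <- dim(vol@voxels)
  new("ModalityVolume", voxels = v, spacingMm = vol@spacingMm,
      modality = vol@modality)
}

# Crop one normalized volume to 80^3 around a 0-based center, padding
# out-of-bounds regions with -1 (the post-normalization minimum).
#' @noRd
.cropVolume <- function(v, center, side = 80L) {
  d <- dim(v)
  half <- side %/% 2L
  out <- array(-1, c(side, side, side))
  c0 <- as.integer(roundHalfUp(center))
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    lo <- c0[ax] - half          # 0-based, half-open [c-40, c+40)
    idx <- seq.int(lo, lo + side - 1L)
    keep <- idx >= 0L & idx <= d[ax] - 1L
    src[[ax]] <- idx[keep] + 1L
    dst[[ax]] <- which(keep)
    if (!any(keep)) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}

#' Crop a series to the 80-voxel lesion box
#'
#' Crops every modality to exactly 80 x 80 x 80 voxels over the half-open
#' range [c - 40, c + 40) per axis around that modality's lesion center,
#' padding out-of-bounds regions with -1. Expects resampled, normalized
#' volumes (values in [-1, 1]).
#'
#' @param series A \linkS4class{PatientSeries}.
#' @param side Crop side length in voxels (default 80).
#' @return A cropped \linkS4class{PatientSeries}; all lesion centers become
#'   the crop center.
#' @export
cropLesion <- function(series, side = 80L) {
  stopifnot(is(series, "PatientSeries"))
  side <- as.integer(side)
  vols <- series@volumes
  for (m in seq_len(7L)) {
    v <- vols[[m]]@voxels
    if (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9) {
      stop("cropLesion expects normalized volumes in [-1, 1]; run ",
           "windowNormalize first (modality ", .MODALITIES[m], ")",
           call. = FALSE)
    }
    ctr <- series@centers[m, ]
    d <- dim(v)
    if (any(ctr < 0) || any(ctr > d - 1)) {
      stop("lesion center outside volume for modality ", .MODALITIES[m],
           call. = FALSE)
    }
    vols[[m]] <- new("ModalityVolume",
                     voxels = .cropVolume(v, ctr, side),
                     spacingMm = vols[[m]]@spacingMm,
                     modality = .MODALITIES[m])
  }
  half <- side %/% 2L
  new("PatientSeries", patientId = series@patientId, label = series@label,
      volumes = vols,
      centers = matrix(rep(as.numeric(half), 21L), 7L, 3L,
                       dimnames = list(.MODALITIES, NULL)))
}

#' Extract paired axial slice packs from a cropped series
#'
#' Cuts the \code{kSlices} consecutive axial (z) slices centered at the
#' crop center from every modality and pairs the seven slices at each
#' position into one \linkS4class{SlicePack}.
#'
#' @param series A cropped \linkS4class{PatientSeries} (80^3 volumes).
#' @param kSlices Odd integer in [1, 80]: number of packs per patient.
#' @return List of \code{kSlices} \linkS4class{SlicePack} objects.
#' @export
extractSlicePacks <- function(series, kSlices = 27L) {
  stopifnot(is(series, "PatientSeries"))
  d <- dim(series@volumes[[1]]@voxels)
  side <- d[1]
  if (!all(vapply(series@volumes, function(v)
    identical(dim(v@voxels), dim(series@volumes[[1]]@voxels)), TRUE))) {
    stop("all modalities must share the cropped grid", call. = FALSE)
  }
  kSlices <- as.integer(kSlices)
  if (is.na(kSlices) || kSlices < 1L || kSlices > d[3] ||
      kSlices %% 2L == 0L) {
    stop("kSlices must be an odd integer in [1, ", d[3], "]", call. = FALSE)
  }
  zc <- d[3] %/% 2L                               # 0-based center slice
  half <- (kSlices - 1L) %/% 2L
  zs <- seq.int(zc - half, zc + half)
  lapply(zs, function(z) {
    sl <- array(0, c(side, side, 7L), dimnames = list(NULL, NULL, .MODALITIES))
    for (m in seq_len(7L)) {
      sl[, , m] <- series@volumes[[m]]@voxels[, , z + 1L]
    }
    new("SlicePack", patientId = series@patientId, zIndex = as.integer(z),
        slices = sl, label = series@label)
  })
}

#' Run the slice-preparation chain on one raw series
#'
#' Applies, in order: isotropic 1 mm resampling (rescaling each modality's
#' lesion center by its spacing), per-modality window normalization, and
#' the 80-voxel lesion crop.
#'
#' @param series A raw \linkS4class{PatientSeries}.
#' @param windows Optional named list of per-modality (lo, hi) windows;
#'   NULL uses the robust percentile default per volume.
#' @return A cropped, normalized \linkS4class{PatientSeries}, ready for
#'   \code{\link{extractSlicePacks}}.
#' @export
preprocessSeries <- function(series, windows = NULL) {
  stopifnot(is(series, "PatientSeries"))
  vols <- series@volumes
  centers <- series@centers
  for (m in seq_len(7L)) {
    sp <- vols[[m]]@spacingMm
    vols[[m]] <- windowNormalize(resampleIsotropic(vols[[m]]), windows)
    centers[m, ] <- roundHalfUp(series@centers[m, ] * sp)
    d <- dim(vols[[m]]@voxels)
    centers[m, ] <- pmin(pmax(centers[m, ], 0), d - 1)
  }
  cropLesion(new("PatientSeries", patientId = series@patientId,
                 label = series@label, volumes = vols, centers = centers))
}
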