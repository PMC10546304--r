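# Tissue class codes shared by rasterization and rendering.
.CLS_BG <- 0L; .CLS_FLUID <- 1L; .CLS_WALL <- 2L
.CLS_SEPTUM <- 3L; .CLS_NODULE <- 4L; .CLS_SCAR <- 5L

#' @noRd
.sampleInt <- function(lo, hi) {
  if (lo >= hi) as.integer(lo) else as.integer(sample(seq.int(lo, hi), 1L))
}

# Rasterize one lesion geometry on the voxel grid (mm geometry converted
# through the T1 spacing; the resulting class map is shared verbatim by all
# seven modalities so their lesion support is identical by construction).
#' @noRd
.rasterLesion <- function(label, cfg, spacing) {
  dims <- cfg@gridDims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  c0 <- floor((dims - 1L) / 2L)                      # 0-based lesion center
  dxs <- (seq_len(nx) - 1L - c0[1]) * spacing[1]
  dys <- (seq_len(ny) - 1L - c0[2]) * spacing[2]
  dzs <- (seq_len(nz) - 1L - c0[3]) * spacing[3]
  R <- 30                                            # mm, lesion bounding ball
  xi <- which(abs(dxs) <= R); yi <- which(abs(dys) <= R)
  zi <- which(abs(dzs) <= R)
  px <- length(xi); py <- length(yi); pz <- length(zi)
  if (px == 0L || py == 0L || pz == 0L) {
    stop("grid too small to contain the lesion", call. = FALSE)
  }
  DX <- rep(dxs[xi], times = py * pz)
  DY <- rep(rep(dys[yi], each = px), times = pz)
  DZ <- rep(dzs[zi], each = px * py)
  lin <- rep(xi, times = py * pz) +
    nx * rep(rep(yi - 1L, each = px), times = pz) +
    (nx * ny) * rep(zi - 1L, each = px * py)
  cls <- integer(px * py * pz)

  typical <- cfg@classGeometry
  scarPresent <- FALSE
  nNodules <- 0L

  if (label == "SCN" && typical) {
    # multicystic cluster, lobulated contour, thin (1-voxel) walls
    nCysts <- .sampleInt(max(2L, cfg@cystCountRange[1]), cfg@cystCountRange[2])
    off <- cbind(stats::runif(nCysts, -10, 10), stats::runif(nCysts, -10, 10),
                 stats::runif(nCysts, -6, 6))
    semi <- matrix(stats::runif(3L * nCysts, cfg@cystRadiusRange[1],
                                cfg@cystRadiusRange[2]), nCysts, 3L)
    t1 <- spacing[1]                                 # 1 in-plane voxel
    for (i in seq_len(nCysts)) {
      qout <- ((DX - off[i, 1]) / (semi[i, 1] + t1))^2 +
        ((DY - off[i, 2]) / (semi[i, 2] + t1))^2 +
        ((DZ - off[i, 3]) / (semi[i, 3] + t1))^2
      cls[qout <= 1] <- .CLS_WALL
    }
    for (i in seq_len(nCysts)) {                     # interiors override walls
      qin <- ((DX - off[i, 1]) / semi[i, 1])^2 +
        ((DY - off[i, 2]) / semi[i, 2])^2 +
        ((DZ - off[i, 3]) / semi[i, 3])^2
      cls[qin <= 1] <- .CLS_FLUID
    }
    scarPresent <- stats::runif(1) < cfg@scarProb
    if (scarPresent) {
      rs <- stats::runif(1, 3, 5)
      cls[DX^2 + DY^2 + DZ^2 <= rs^2] <- .CLS_SCAR
    }
  } else {
    # solitary cyst with thick uneven wall, septations and mural nodules
    # (the MCN morphology; also the shared geometry when classGeometry is
    # off, where only enhancement may separate the classes)
    nCysts <- 1L
    a <- stats::runif(1, cfg@mcnRadiusRange[1], cfg@mcnRadiusRange[2])
    b <- stats::runif(1, cfg@mcnRadiusRange[1], cfg@mcnRadiusRange[2])
    cc <- 0.75 * stats::runif(1, cfg@mcnRadiusRange[1], cfg@mcnRadiusRange[2])
    tvox <- .sampleInt(cfg@wallThicknessRange[1], cfg@wallThicknessRange[2])
    t0 <- tvox * spacing[1]
    phi <- stats::runif(1, 0, 2 * pi)
    theta <- atan2(DY, DX)
    tl <- t0 * (1 + 0.3 * sin(2 * theta + phi))      # uneven thickness
    qout <- (DX / (a + tl))^2 + (DY / (b + tl))^2 + (DZ / (cc + tl))^2
    cls[qout <= 1] <- .CLS_WALL
    qin <- (DX / a)^2 + (DY / b)^2 + (DZ / cc)^2
    cls[qin <= 1] <- .CLS_FLUID
    nSepta <- .sampleInt(1L, 2L)
    for (i in seq_len(nSepta)) {
      psi <- stats::runif(1, 0, 2 * pi)
      nvec <- c(cos(psi), sin(psi), stats::runif(1, -0.2, 0.2))
      nvec <- nvec / sqrt(sum(nvec^2))
      d0 <- stats::runif(1, -0.3, 0.3) * a
      sep <- abs(DX * nvec[1] + DY * nvec[2] + DZ * nvec[3] - d0) <= 0.6
      cls[sep & cls == .CLS_FLUID] <- .CLS_SEPTUM
    }
    nNodules <- .sampleInt(cfg@noduleCountRange[1], cfg@noduleCountRange[2])
    for (i in seq_len(nNodules)) {
      tn <- stats::runif(1, 0, 2 * pi)
      zn <- stats::runif(1, -0.5, 0.5)
      p <- 0.95 * c(a * cos(tn) * sqrt(1 - zn^2), b * sin(tn) * sqrt(1 - zn^2),
                    cc * zn)
      rn <- stats::runif(1, cfg@noduleRadiusRange[1], cfg@noduleRadiusRange[2])
      nod <- (DX - p[1])^2 + (DY - p[2])^2 + (DZ - p[3])^2 <= rn^2
      cls[nod] <- .CLS_NODULE
    }
  }

  classMap <- integer(prod(dims))
  classMap[lin] <- cls
  dim(classMap) <- dims
  list(classMap = classMap, nCysts = nCysts, nNodules = nNodules,
       scarPresent = scarPresent, center = as.numeric(c0))
}

# Raw intensity (arbitrary MR-like units) of each tissue class for modality
# index m; enh is the additive wall enhancement of this phantom's class.
#' @noRd
.classIntensity <- function(m, enh) {
  isT2 <- m == 7L
  fluid <- if (isT2) 300 else 60
  wall <- (if (isT2) 140 else 110) + enh[m]
  scar <- if (isT2) 80 else 100 + 30 * .PHASE_FRAC[m]
  c(100, fluid, wall, wall, wall + 10, scar)         # bg,fluid,wall,sep,nod,scar
}

# Rigid integer translation of a 3D array, vacated voxels filled.
#' @noRd
.shiftArray <- function(arr, shift, fill = 0L) {
  if (all(shift == 0)) return(arr)
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    dst[[ax]] <- seq.int(max(1L, 1L + s), min(d[ax], d[ax] + s))
    src[[ax]] <- dst[[ax]] - s
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate one synthetic seven-modality patient series
#'
#' Builds a single lesion geometry (shared "content") and renders it under
#' seven modality-specific intensity maps (distinct "appearance"): cyst
#' fluid is dark on the T1 phases and bright on T2, and wall/nodule/septum
#' intensity ramps up across the contrast phases
#' T1pre -> T1a1 -> T1a2 -> T1v1 -> T1v2 -> T1post with a class-dependent
#' slope (steeper for MCN). A smooth per-modality bias field, Gaussian
#' noise, and an optional per-modality rigid integer misalignment are
#' added. The output is fully determined by \code{(label, config)},
#' including \code{config@seed}.
#'
#' @param label \code{"SCN"} or \code{"MCN"}.
#' @param config A \linkS4class{PhantomConfig}.
#' @param patientId Identifier stored in the returned series.
#' @return A list with elements \code{series} (\linkS4class{PatientSeries})
#'   and \code{truth} (\linkS4class{PhantomTruth}); the truth carries the
#'   pre-misalignment voxel indices of every lesion compartment so tests
#'   can read, e.g., wall voxels analytically.
#' @examples
#' ph <- generatePhantom("MCN", phantomConfig(seed = 7))
#' ph$truth
#' @export
generatePhantom <- function(label, config = phantomConfig(),
                            patientId = "P001") {
  checkLabel(label)
  validObject(config)
  withSeed(config@seed, {
    dims <- config@gridDims
    n <- prod(dims)
    sIn1 <- stats::runif(1, config@spacingT1Range[1, 1],
                         config@spacingT1Range[2, 1])
    sZ1 <- stats::runif(1, config@spacingT1Range[1, 3],
                        config@spacingT1Range[2, 3])
    spT1 <- c(sIn1, sIn1, sZ1)
    sIn2 <- stats::runif(1, config@spacingT2Range[1, 1],
                         config@spacingT2Range[2, 1])
    sZ2 <- stats::runif(1, config@spacingT2Range[1, 3],
                        config@spacingT2Range[2, 3])
    spT2 <- c(sIn2, sIn2, sZ2)

    geo <- .rasterLesion(label, config, spT1)
    classMap <- geo$classMap

    shifts <- matrix(0L, 7L, 3L, dimnames = list(.MODALITIES, NULL))
    if (config@misalignmentSd > 0) {
      shifts[] <- as.integer(roundHalfUp(
        stats::rnorm(21L, 0, config@misalignmentSd)))
    }

    enh <- if (label == "MCN") config@enhancementMcn else config@enhancementScn
    gx <- seq(-1, 1, length.out = dims[1])
    gy <- seq(-1, 1, length.out = dims[2])
    gz <- seq(-1, 1, length.out = dims[3])
    # one smooth low-order bias field per patient (session-level), shared by
    # all modalities
    bc <- stats::runif(3, -1, 1)
    bias <- 10 * (rep(bc[1] * gx, times = dims[2] * dims[3]) +
                  rep(rep(bc[2] * gy, each = dims[1]), times = dims[3]) +
                  rep(bc[3] * gz, each = dims[1] * dims[2]))

    vols <- vector("list", 7L)
    names(vols) <- .MODALITIES
    for (m in seq_len(7L)) {
      cm <- .shiftArray(classMap, shifts[m, ])
      it <- .classIntensity(m, enh)
      v <- it[cm + 1L] + bias
      if (config@noiseSd > 0) {
        v <- v + stats::rnorm(n, 0, config@noiseSd)
      }
      dim(v) <- dims
      vols[[m]] <- new("ModalityVolume", voxels = v,
                       spacingMm = if (m == 7L) spT2 else spT1,
                       modality = .MODALITIES[m])
    }

    roi <- list(fluid = which(classMap == .CLS_FLUID),
                wall = which(classMap == .CLS_WALL),
                septum = which(classMap == .CLS_SEPTUM),
                nodule = which(classMap == .CLS_NODULE),
                scar = which(classMap == .CLS_SCAR))
    truth <- new("PhantomTruth", label = label,
                 scarPresent = geo$scarPresent, nCysts = geo$nCysts,
                 nNodules = geo$nNodules, lesionCenter = geo$center,
                 shifts = shifts, roi = roi)
    series <- new("PatientSeries", patientId = patientId, label = label,
                  volumes = vols,
                  centers = matrix(rep(geo$center, each = 7L), 7L, 3L,
                                   dimnames = list(.MODALITIES, NULL)))
    list(series = series, truth = truth)
  })
}

#' Generate a synthetic cohort
#'
#' Generates \code{nScn + nMcn} phantom patients with unique ids; each
#' patient's seed is derived deterministically from \code{config@seed}, so
#' the whole cohort is reproducible from one integer.
#'
#' @param nScn,nMcn Nonnegative counts of SCN and MCN patients.
#' @param config A \linkS4class{PhantomConfig}; its seed is the cohort seed.
#' @return A list of \code{list(series=, truth=)} pairs, SCN patients first.
#' @examples
#' coh <- generateCohort(2, 1, phantomConfig(seed = 3))
#' vapply(coh, function(p) seriesLabel(p$series), "")
#' @export
generateCohort <- function(nScn, nMcn, config = phantomConfig()) {
  if (length(nScn) != 1L || length(nMcn) != 1L || is.na(nScn) || is.na(nMcn) ||
      nScn < 0 || nMcn < 0) {
    stop("nScn and nMcn must be nonnegative counts", call. = FALSE)
  }
  labels <- rep(c("SCN", "MCN"), times = c(nScn, nMcn))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, i)
    out[[i]] <- generatePhantom(labels[i], cfg,
                                patientId = sprintf("P%03d", i))
  }
  out
}
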