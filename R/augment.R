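# Rotate a square slice by angleDeg around its center with bilinear
# interpolation; regions rotated in from outside are filled with -1.
#' @noRd
.rotateSlice <- function(mat, angleDeg) {
  if (angleDeg == 0) return(mat)
  n <- nrow(mat)
  th <- angleDeg * pi / 180
  c0 <- (n - 1) / 2
  ij <- expand.grid(i = seq_len(n) - 1, j = seq_len(n) - 1)
  di <- ij$i - c0; dj <- ij$j - c0
  # inverse mapping: sample the source at the backward-rotated position
  si <- cos(th) * di + sin(th) * dj + c0
  sj <- -sin(th) * di + cos(th) * dj + c0
  i0 <- floor(si); j0 <- floor(sj)
  wi <- si - i0; wj <- sj - j0
  ok <- i0 >= 0 & j0 >= 0 & i0 <= n - 2 & j0 <= n - 2
  out <- rep(-1, n * n)
  if (any(ok)) {
    i0k <- i0[ok] + 1L; j0k <- j0[ok] + 1L
    wik <- wi[ok]; wjk <- wj[ok]
    v00 <- mat[cbind(i0k, j0k)];     v10 <- mat[cbind(i0k + 1L, j0k)]
    v01 <- mat[cbind(i0k, j0k + 1L)]; v11 <- mat[cbind(i0k + 1L, j0k + 1L)]
    out[ok] <- (1 - wik) * (1 - wjk) * v00 + wik * (1 - wjk) * v10 +
      (1 - wik) * wjk * v01 + wik * wjk * v11
  }
  matrix(out, n, n)
}

#' Augment a slice pack
#'
#' Applies one random geometric transform - horizontal flip, vertical
#' flip, or rotation within \code{+/- rotationRange} degrees - identically
#' to all seven modality slices (so their spatial pairing is preserved),
#' followed by an independent per-modality intensity jitter
#' (multiplicative scale in \code{1 +/- jitterScale}, additive shift in
#' \code{+/- jitterShift}, re-clipped to [-1, 1]). Fully determined by
#' \code{seed}.
#'
#' With \code{flipProb = 0}, \code{rotationRange = 0},
#' \code{jitterScale = 0} and \code{jitterShift = 0} the pack is returned
#' unchanged.
#'
#' @param pack A \linkS4class{SlicePack}.
#' @param seed Integer seed.
#' @param flipProb Probability that the geometric transform is a flip
#'   (split evenly between horizontal and vertical); otherwise a rotation
#'   is drawn.
#' @param rotationRange Maximum absolute rotation in degrees.
#' @param jitterScale,jitterShift Half-widths of the per-modality intensity
#'   scale and shift jitters.
#' @return An augmented \linkS4class{SlicePack}.
#' @export
augmentPack <- function(pack, seed, flipProb = 0.5, rotationRange = 15,
                        jitterScale = 0.05, jitterShift = 0.05) {
  stopifnot(is(pack, "SlicePack"))
  withSeed(seed, {
    sl <- pack@slices
    n <- dim(sl)[1]
    u <- stats::runif(1)
    if (u < flipProb / 2) {
      sl <- sl[, n:1, , drop = FALSE]                 # horizontal flip
    } else if (u < flipProb) {
      sl <- sl[n:1, , , drop = FALSE]                 # vertical flip
    } else {
      ang <- stats::runif(1, -rotationRange, rotationRange)
      if (ang != 0) {
        for (m in seq_len(7L)) sl[, , m] <- .rotateSlice(sl[, , m], ang)
      }
    }
    for (m in seq_len(7L)) {
      sc <- stats::runif(1, 1 - jitterScale, 1 + jitterScale)
      sh <- stats::runif(1, -jitterShift, jitterShift)
      if (sc != 1 || sh != 0) {
        sl[, , m] <- pmin(pmax(sl[, , m] * sc + sh, -1), 1)
      }
    }
    dimnames(sl) <- list(NULL, NULL, .MODALITIES)
    new("SlicePack", patientId = pack@patientId, zIndex = pack@zIndex,
        slices = sl, label = pack@label)
  })
}

#' Expand a training set with augmented copies
#'
#' Each pack yields itself plus \code{nAug} augmented copies with seeds
#' derived deterministically from \code{seed}.
#'
#' @param packs List of \linkS4class{SlicePack}.
#' @param nAug Number of augmented copies per pack (default 3).
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{augmentPack}}.
#' @return List of \code{length(packs) * (1 + nAug)} packs.
#' @export
augmentPacks <- function(packs, nAug = 3L, seed = 1L, ...) {
  out <- vector("list", length(packs) * (1L + nAug))
  k <- 0L
  for (i in seq_along(packs)) {
    k <- k + 1L
    out[[k]] <- packs[[i]]
    for (j in seq_len(nAug)) {
      k <- k + 1L
      out[[k]] <- augmentPack(packs[[i]], deriveSeed(seed, i * 1000L + j), ...)
    }
  }
  out
}
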