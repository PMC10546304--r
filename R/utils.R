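#' Canonical modality names
#'
#' The seven MRI modalities handled by the package, in canonical order:
#' the T1-weighted contrast phases (pre-contrast, early/late arterial,
#' early/late venous, delayed) followed by T2. All fusion operations,
#' slice packs and manifests use this order.
#'
#' @return Character vector of length 7.
#' @export
canonicalModalities <- function() {
  c("T1pre", "T1a1", "T1a2", "T1v1", "T1v2", "T1post", "T2")
}

#' @noRd
.MODALITIES <- c("T1pre", "T1a1", "T1a2", "T1v1", "T1v2", "T1post", "T2")

# fraction of the contrast time-course covered by each modality; T2 is not a
# contrast phase and sits at 0
.PHASE_FRAC <- c(0, 0.2, 0.4, 0.6, 0.8, 1, 0)

#' @noRd
.LABELS <- c("SCN", "MCN")

#' Round half away from zero
#'
#' Deterministic rounding used wherever voxel dimensions or centers are
#' derived from millimetre quantities; base \code{round()} rounds half to
#' even, which would make resampled grid sizes depend on parity.
#' @noRd
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @noRd
checkLabel <- function(label) {
  if (!(is.character(label) && length(label) == 1L && label %in% .LABELS)) {
    stop("label must be one of ", paste(.LABELS, collapse = ", "),
         ", got: ", paste(label, collapse = ","), call. = FALSE)
  }
  label
}

#' @noRd
checkModality <- function(modality) {
  if (!(is.character(modality) && length(modality) == 1L &&
        modality %in% .MODALITIES)) {
    stop("modality must be one of ", paste(.MODALITIES, collapse = ", "),
         call. = FALSE)
  }
  modality
}

# Derive a child RNG seed from a parent seed and an index; keeps results
# below 2^31 so they remain valid R integers.
#' @noRd
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483562) + 1L
}

#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
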