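# Shared fixtures, all generated in code.

modalities <- canonicalModalities()

# A quiet phantom configuration for geometry-level assertions.
quietConfig <- function(seed = 1L, ...) {
  phantomConfig(noiseSd = 0, misalignmentSd = 0, seed = seed, ...)
}

# A random valid FeatureSet.
randomFeatureSet <- function(D = 5L, La = 2L, seed = 1L) {
  set.seed(seed)
  featureSet(matrix(rnorm(7 * D), 7L, D), La = La)
}

# A slice pack filled from a function of (modality index).
makePack <- function(fill, patientId = "P001", label = "MCN", z = 40L,
                     side = 80L) {
  sl <- array(0, c(side, side, 7L))
  for (m in 1:7) sl[, , m] <- fill(m)
  dimnames(sl) <- list(NULL, NULL, modalities)
  new("SlicePack", patientId = patientId, zIndex = as.integer(z),
      slices = sl, label = label)
}

# A linearly separable synthetic slice-pack cohort: class shifts the mean
# slice intensity, plus mild texture noise. nPerClass patients, one pack
# per patient unless packsPer > 1.
separablePacks <- function(nPerClass = 8L, packsPer = 1L, delta = 0.25,
                           noise = 0.05, seed = 1L, side = 80L) {
  set.seed(seed)
  packs <- list()
  pid <- 0L
  for (lab in c("SCN", "MCN")) {
    mu <- if (lab == "MCN") delta else -delta
    for (i in seq_len(nPerClass)) {
      pid <- pid + 1L
      for (z in seq_len(packsPer)) {
        packs[[length(packs) + 1L]] <- makePack(
          function(m) pmin(pmax(mu + matrix(rnorm(side * side, 0, noise),
                                            side, side), -1), 1),
          patientId = sprintf("P%03d", pid), label = lab,
          z = 39L + z, side = side)
      }
    }
  }
  packs
}

# Brute-force pairwise Mann-Whitney AUC oracle (ties count half).
aucPairwiseOracle <- function(scores, labels) {
  pos <- scores[labels == "MCN"]
  neg <- scores[labels != "MCN"]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}
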