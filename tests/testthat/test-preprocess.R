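mkvol <- function(dims, spacing, modality = "T1pre", fill = 0) {
  new("ModalityVolume", voxels = array(fill, dims),
      spacingMm = spacing, modality = modality)
}

test_that("resampled dimensions follow round(dims x spacing)", {
  v1 <- mkvol(c(256, 256, 40), c(0.78, 0.78, 2.59))
  expect_identical(dim(voxels(resampleIsotropic(v1))), c(200L, 200L, 104L))
  v2 <- mkvol(c(320, 320, 30), c(0.625, 0.625, 4.80), "T2")
  expect_identical(dim(voxels(resampleIsotropic(v2))), c(200L, 200L, 144L))
  # .5 products round away from zero, not to even
  v3 <- mkvol(c(10, 10, 10), c(0.25, 0.25, 0.25))
  expect_identical(dim(voxels(resampleIsotropic(v3))), c(3L, 3L, 3L))
  expect_identical(spacingMm(resampleIsotropic(v1)), c(1, 1, 1))
})

test_that("resampling at unit spacing is the identity", {
  set.seed(2)
  arr <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  v <- new("ModalityVolume", voxels = arr, spacingMm = c(1, 1, 1),
           modality = "T1a1")
  expect_identical(voxels(resampleIsotropic(v)), arr)
})

test_that("trilinear resampling reproduces linear fields exactly", {
  # a trilinear interpolant is exact on trilinear functions (away from the
  # clamped border)
  dims <- c(21, 21, 11)
  sp <- c(1.5, 1.5, 2)
  xs <- (seq_len(dims[1]) - 1) * sp[1]
  ys <- (seq_len(dims[2]) - 1) * sp[2]
  zs <- (seq_len(dims[3]) - 1) * sp[3]
  arr <- outer(outer(2 * xs, 3 * ys, "+"), 5 * zs, "+")
  v <- new("ModalityVolume", voxels = arr, spacingMm = sp, modality = "T1v1")
  out <- voxels(resampleIsotropic(v))
  d <- dim(out)
  xo <- (seq_len(d[1]) - 1); yo <- (seq_len(d[2]) - 1); zo <- (seq_len(d[3]) - 1)
  expected <- outer(outer(2 * xo, 3 * yo, "+"), 5 * zo, "+")
  interior <- out[xo + 1 <= max(xs), yo + 1 <= max(ys), zo + 1 <= max(zs)]
  expEx <- expected[xo + 1 <= max(xs), yo + 1 <= max(ys), zo + 1 <= max(zs)]
  expect_lt(max(abs(interior - expEx)), 1e-9)
})

test_that("window normalization maps the window onto [-1, 1]", {
  v <- mkvol(c(2, 2, 2), c(1, 1, 1))
  arr <- array(c(0, 100, 200, 300, 50, -10, 150, 200), c(2, 2, 2))
  v@voxels <- arr
  out <- voxels(windowNormalize(v, c(0, 200)))
  expect_equal(out[1, 1, 1], -1)          # v = lo
  expect_equal(out[1, 2, 1], 1)           # v = hi
  expect_equal(out[2, 1, 1], 0)           # midpoint
  expect_equal(out[1, 1, 2], -0.5)        # lo=0, hi=200, v=50
  expect_equal(out[2, 2, 1], 1)           # 300 clipped to hi
  expect_equal(out[2, 1, 2], -1)          # -10 clipped to lo
  expect_true(all(out >= -1 & out <= 1))
  expect_error(windowNormalize(v, c(200, 0)), "lo must be")
})

test_that("window normalization is monotone nondecreasing", {
  set.seed(3)
  vals <- sort(runif(50, -50, 350))
  v <- new("ModalityVolume", voxels = array(vals, c(50, 1, 1)),
           spacingMm = c(1, 1, 1), modality = "T1post")
  out <- as.vector(voxels(windowNormalize(v, c(10, 290))))
  expect_true(all(diff(out) >= 0))
})

test_that("per-modality window lists are honored", {
  v <- mkvol(c(2, 1, 1), c(1, 1, 1), modality = "T2")
  v@voxels <- array(c(100, 300), c(2, 1, 1))
  spec <- list(T2 = c(100, 300), T1pre = c(0, 1))
  out <- voxels(windowNormalize(v, spec))
  expect_equal(as.vector(out), c(-1, 1))
})

test_that("lesion crop yields exactly 80^3 with -1 padding at boundaries", {
  coh <- generateCohort(0, 1, quietConfig(seed = 12L))
  cropped <- preprocessSeries(coh[[1]]$series)
  for (m in modalities) {
    expect_identical(dim(voxels(modalityVolumes(cropped)[[m]])),
                     c(80L, 80L, 80L))
  }
  expect_identical(unname(lesionCenters(cropped)[6, ]), c(40, 40, 40))

  # explicit padding arithmetic: center x = 10 in a 100-wide axis leaves
  # the first 30 yz-planes at the padding value
  arr <- array(0.5, c(100, 100, 100))
  vols <- lapply(modalities, function(m)
    new("ModalityVolume", voxels = arr, spacingMm = c(1, 1, 1), modality = m))
  names(vols) <- modalities
  centers <- matrix(rep(c(10, 50, 50), each = 7), 7, 3)
  s <- new("PatientSeries", patientId = "PX", label = "SCN",
           volumes = vols, centers = centers)
  out <- voxels(modalityVolumes(cropLesion(s))$T1pre)
  expect_true(all(out[1:30, , ] == -1))
  expect_true(all(out[31:80, , ] == 0.5))

  # centered crop with >= 40 voxels of margin copies the source subarray
  set.seed(4)
  arr2 <- array(runif(100^3, -1, 1), c(100, 100, 100))
  vols2 <- lapply(modalities, function(m)
    new("ModalityVolume", voxels = arr2, spacingMm = c(1, 1, 1),
        modality = m))
  names(vols2) <- modalities
  s2 <- new("PatientSeries", patientId = "PY", label = "MCN",
            volumes = vols2,
            centers = matrix(rep(50, 21), 7, 3))
  out2 <- voxels(modalityVolumes(cropLesion(s2))$T1a1)
  expect_identical(out2, arr2[11:90, 11:90, 11:90])
})

test_that("slice packs pair the seven modalities at the same position", {
  coh <- generateCohort(1, 0, quietConfig(seed = 13L))
  cropped <- preprocessSeries(coh[[1]]$series)
  packs <- extractSlicePacks(cropped, 1L)
  expect_length(packs, 1L)
  expect_identical(packs[[1]]@zIndex, 40L)
  packs27 <- extractSlicePacks(cropped, 27L)
  expect_length(packs27, 27L)
  expect_identical(vapply(packs27, function(p) p@zIndex, 0L),
                   seq(27L, 53L))
  for (p in packs27[c(1, 14, 27)]) {
    expect_identical(dim(p@slices), c(80L, 80L, 7L))
    expect_true(all(p@slices >= -1 & p@slices <= 1))
    for (m in seq_len(7)) {
      expect_identical(p@slices[, , m],
                       voxels(modalityVolumes(cropped)[[m]])[, , p@zIndex + 1])
    }
  }
  expect_error(extractSlicePacks(cropped, 4L), "odd")
  expect_error(extractSlicePacks(cropped, 81L), "odd integer in")
})

test_that("augmentation with everything disabled is the identity", {
  p <- makePack(function(m) matrix(runif(6400, -1, 1), 80, 80))
  out <- augmentPack(p, seed = 5L, flipProb = 0, rotationRange = 0,
                     jitterScale = 0, jitterShift = 0)
  expect_identical(out@slices, p@slices)
})

test_that("augmentation is seeded and applies geometry jointly", {
  set.seed(6)
  p <- makePack(function(m) matrix(runif(6400, -1, 1), 80, 80))
  a1 <- augmentPack(p, seed = 7L)
  a2 <- augmentPack(p, seed = 7L)
  expect_identical(a1@slices, a2@slices)
  expect_false(identical(augmentPack(p, seed = 8L)@slices, a1@slices))

  # with flipProb = 1 and seed 1 the first uniform draw selects the
  # horizontal flip: pixel (i, j) -> (i, 79 - j) in every modality
  h <- augmentPack(p, seed = 1L, flipProb = 1, rotationRange = 0,
                   jitterScale = 0, jitterShift = 0)
  set.seed(1L)
  expect_lt(runif(1), 0.5)   # confirms the branch taken
  for (m in 1:7) {
    expect_identical(h@slices[, , m], p@slices[, 80:1, m])
  }
})

test_that("rotation commutes with modality selection", {
  p <- makePack(function(m) matrix(runif(6400, -1, 1), 80, 80))
  a <- augmentPack(p, seed = 9L, flipProb = 0, rotationRange = 15,
                   jitterScale = 0, jitterShift = 0)
  # recover the drawn angle and check each modality independently
  set.seed(9L)
  runif(1)
  ang <- runif(1, -15, 15)
  for (m in c(1, 4, 7)) {
    expect_equal(a@slices[, , m],
                 cystfuse:::.rotateSlice(p@slices[, , m], ang))
  }
})

test_that("augmentPacks yields originals plus n augmented copies", {
  p <- makePack(function(m) matrix(0.1 * m, 80, 80))
  out <- augmentPacks(list(p, p), nAug = 3L, seed = 2L)
  expect_length(out, 8L)
  expect_identical(out[[1]]@slices, p@slices)
  expect_identical(out[[5]]@slices, p@slices)
})
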