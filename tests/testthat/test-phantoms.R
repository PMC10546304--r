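test_that("phantom generation is fully determined by label and config", {
  cfg <- phantomConfig(seed = 11L, misalignmentSd = 0.8)
  a <- generatePhantom("SCN", cfg)
  b <- generatePhantom("SCN", cfg)
  for (m in modalities) {
    expect_identical(voxels(modalityVolumes(a$series)[[m]]),
                     voxels(modalityVolumes(b$series)[[m]]))
  }
  expect_identical(a$truth@roi, b$truth@roi)
  expect_identical(a$truth@shifts, b$truth@shifts)
  # a different seed changes the volumes
  c2 <- generatePhantom("SCN", phantomConfig(seed = 12L,
                                             misalignmentSd = 0.8))
  expect_false(identical(voxels(modalityVolumes(a$series)$T1pre),
                         voxels(modalityVolumes(c2$series)$T1pre)))
})

test_that("noise-free phantoms share one lesion support across modalities", {
  for (lab in c("SCN", "MCN")) {
    ph <- generatePhantom(lab, quietConfig(seed = if (lab == "SCN") 3L
                                           else 4L))
    vols <- lapply(modalityVolumes(ph$series), voxels)
    # cross-modality differencing cancels the shared background (tissue +
    # bias), so the union of pairwise differences is exactly the voxels
    # whose tissue class renders differently in some modality
    diffSupport <- Reduce(`|`, lapply(2:7, function(m)
      vols[[m]] != vols[[1]]))
    roiUnion <- sort(unique(unlist(ph$truth@roi)))
    expect_identical(which(diffSupport), roiUnion)
  }
})

test_that("every pair of modalities differs on lesion voxels", {
  ph <- generatePhantom("MCN", quietConfig(seed = 5L))
  vols <- lapply(modalityVolumes(ph$series), voxels)
  roi <- unlist(ph$truth@roi)
  for (m in 1:6) for (n in (m + 1):7) {
    expect_true(any(vols[[m]][roi] != vols[[n]][roi]),
                info = sprintf("modalities %d vs %d", m, n))
  }
})

test_that("wall enhancement ramps monotonically over the contrast phases", {
  for (seed in c(21L, 22L)) {
    for (lab in c("SCN", "MCN")) {
      ph <- generatePhantom(lab, quietConfig(seed = seed))
      wall <- ph$truth@roi$wall
      expect_gt(length(wall), 0L)
      means <- vapply(1:6, function(m)
        mean(voxels(modalityVolumes(ph$series)[[m]])[wall]), 0)
      expect_true(all(diff(means) >= -1e-9))
      # delayed phase strictly brighter than pre-contrast
      expect_gt(means[6], means[1])
    }
  }
})

test_that("MCN delayed-phase enhancement exceeds the SCN slope", {
  scn <- generatePhantom("SCN", quietConfig(seed = 31L))
  mcn <- generatePhantom("MCN", quietConfig(seed = 31L))
  ramp <- function(ph) {
    wall <- ph$truth@roi$wall
    mean(voxels(modalityVolumes(ph$series)$T1post)[wall]) -
      mean(voxels(modalityVolumes(ph$series)$T1pre)[wall])
  }
  expect_gt(ramp(mcn), ramp(scn))
})

test_that("class-typical morphology matches the configured geometry", {
  scn <- generatePhantom("SCN", quietConfig(seed = 41L))
  expect_gte(scn$truth@nCysts, 2L)              # multicystic
  expect_identical(scn$truth@nNodules, 0L)
  mcn <- generatePhantom("MCN", quietConfig(seed = 42L))
  expect_identical(mcn$truth@nCysts, 1L)        # solitary
  expect_gte(mcn$truth@nNodules, 1L)
  expect_gt(length(mcn$truth@roi$septum), 0L)
  expect_false(mcn$truth@scarPresent)
})

test_that("misalignment shifts each modality's geometry rigidly", {
  cfg <- phantomConfig(noiseSd = 0, misalignmentSd = 1.5, seed = 51L)
  ph <- generatePhantom("MCN", cfg)
  expect_true(any(ph$truth@shifts != 0L))
  # reference rendering without misalignment from the same seed has
  # identical geometry, so shifted wall voxels must land where the truth
  # says
  ph0 <- generatePhantom("MCN", phantomConfig(noiseSd = 0,
                                              misalignmentSd = 0,
                                              seed = 51L))
  expect_identical(ph$truth@roi, ph0$truth@roi)
})

test_that("generateCohort returns the requested composition deterministically", {
  cfg <- quietConfig(seed = 61L)
  coh <- generateCohort(2, 3, cfg)
  expect_length(coh, 5L)
  labs <- vapply(coh, function(p) seriesLabel(p$series), "")
  expect_identical(sum(labs == "SCN"), 2L)
  expect_identical(sum(labs == "MCN"), 3L)
  ids <- vapply(coh, function(p) patientId(p$series), "")
  expect_false(anyDuplicated(ids) > 0L)
  coh2 <- generateCohort(2, 3, cfg)
  expect_identical(voxels(modalityVolumes(coh[[4]]$series)$T2),
                   voxels(modalityVolumes(coh2[[4]]$series)$T2))
  expect_length(generateCohort(0, 0, cfg), 0L)
  expect_error(generateCohort(-1, 2, cfg), "nonnegative")
})

test_that("a full 33/36 cohort has the requested composition", {
  coh <- generateCohort(33, 36, quietConfig(seed = 62L))
  expect_length(coh, 69L)
  labs <- vapply(coh, function(p) seriesLabel(p$series), "")
  expect_identical(sum(labs == "SCN"), 33L)
  expect_identical(sum(labs == "MCN"), 36L)
  ids <- vapply(coh, function(p) patientId(p$series), "")
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("invalid phantom inputs are rejected", {
  expect_error(generatePhantom("IPMN", quietConfig()), "label")
  # grid too small to contain the 80 mm crop
  expect_error(phantomConfig(gridDims = c(40L, 40L, 20L)), "80 mm crop")
  expect_error(phantomConfig(scarProb = 1.3), "scarProb")
})

test_that("T2 draws the larger axial spacing range", {
  ph <- generatePhantom("SCN", quietConfig(seed = 71L))
  spT2 <- spacingMm(modalityVolumes(ph$series)$T2)
  spT1 <- spacingMm(modalityVolumes(ph$series)$T1pre)
  expect_gte(spT2[3], 4.80)
  expect_lte(spT2[3], 8.40)
  expect_gte(spT1[3], 2.50)
  expect_lte(spT1[3], 2.59)
  expect_gt(spT2[3], spT1[3])
})
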