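test_that("trophic-group presets encode the documented movement contrasts", {
  bact <- wormPreset("bacterial_feeder")
  plant <- wormPreset("plant_feeder")
  tri <- wormPreset("trichodorus")
  expect_gt(bact@undulationWavelength, plant@undulationWavelength)
  expect_lt(bact@undulationAmplitudePx, plant@undulationAmplitudePx)
  expect_true(bact@headOscillation)
  expect_false(plant@headOscillation)
  expect_true(plant@sporadic)
  expect_lt(tri@speedPxPerFrame, 0.05)      # near-stationary
  expect_gt(tri@activity, 0)                # alive but still
  expect_error(wormPreset("fungivore"))
})

test_that("identical seeds give bit-identical scans", {
  scene <- sceneSpec(nWorms = 2L, width = 32L, height = 32L, depth = 3L,
                     mixingLayerZ = c(0, 3), framesPerStep = 4L)
  s1 <- simulateScan(scene, seed = 99)
  s2 <- simulateScan(scene, seed = 99)
  for (z in seq_along(s1$stacks))
    expect_identical(frames(s1$stacks[[z]]), frames(s2$stacks[[z]]))
  expect_identical(s1$groundTruth$track, s2$groundTruth$track)
  s3 <- simulateScan(scene, seed = 100)
  expect_false(identical(frames(s1$stacks[[1]]), frames(s3$stacks[[1]])))
})

test_that("a dead worm is as static as the background", {
  scene <- sceneSpec(nWorms = 1L, width = 48L, height = 48L, depth = 4L,
                     mixingLayerZ = c(1, 3), framesPerStep = 12L)
  scan <- simulateScan(scene, list(deadWorm()), seed = 7)
  fp <- scan$groundTruth$footprints[[1]]
  z0 <- fp[1, "z"]
  sel <- fp[fp[, "z"] == z0, , drop = FALSE]
  arr <- frames(scan$stacks[[z0 + 1]])
  wormIdx <- cbind(sel[, "y"] + 1, sel[, "x"] + 1)
  pixVar <- function(idx) {
    vals <- apply(arr, 3, function(f) f[idx])
    mean(apply(vals, 1, stats::var))
  }
  vw <- pixVar(wormIdx)
  # background pixels: everything outside the footprint on that slice
  bgMask <- matrix(TRUE, 48, 48); bgMask[wormIdx] <- FALSE
  bgIdx <- which(bgMask, arr.ind = TRUE)[seq_len(nrow(wormIdx)) * 3, ]
  vb <- pixVar(bgIdx)
  expect_gt(vw / vb, 0.8)
  expect_lt(vw / vb, 1.25)
})

test_that("a fully active worm lights up the activity map far above background", {
  ratios <- vapply(c(51, 52, 53), function(seed) {
    wm <- wormPreset("trichodorus"); wm@activity <- 1
    scene <- sceneSpec(nWorms = 1L, width = 48L, height = 48L,
                       depth = 4L, mixingLayerZ = c(1, 3),
                       framesPerStep = 12L)
    scan <- simulateScan(scene, list(wm), seed)
    vol <- stackMaps(lapply(scan$stacks, generalizedDifferences),
                     25, 62.5)
    fp <- scan$groundTruth$footprints[[1]]
    idx <- cbind(fp[, "y"] + 1, fp[, "x"] + 1, fp[, "z"] + 1)
    wormMean <- mean(voxels(vol)[idx])
    all <- voxels(vol)
    bgMean <- (sum(all) - sum(all[idx])) / (length(all) - nrow(idx))
    wormMean / bgMean
  }, numeric(1))
  expect_true(all(ratios > 5))
})

test_that("worms initialized outside the volume are rejected", {
  wm <- wormPreset("bacterial_feeder")
  wm@position <- c(200, 10)
  expect_error(simulateScan(sceneSpec(nWorms = 1L), list(wm), 1),
               "outside the volume")
  wm2 <- wormPreset("bacterial_feeder")
  wm2@zCenter <- 40
  expect_error(simulateScan(sceneSpec(nWorms = 1L), list(wm2), 1),
               "outside the volume")
})

test_that("ground-truth footprints cover the worm's imaged slices", {
  scene <- sceneSpec(nWorms = 1L, width = 40L, height = 40L, depth = 6L,
                     mixingLayerZ = c(2, 4), framesPerStep = 4L)
  scan <- simulateScan(scene, seed = 17)
  fp <- scan$groundTruth$footprints[[1]]
  expect_gt(nrow(fp), 50)
  expect_true(all(fp[, "x"] >= 0 & fp[, "x"] < 40))
  expect_true(all(fp[, "z"] >= 0 & fp[, "z"] < 6))
  # the worm drifts in z but stays within the mixing layer band
  expect_true(all(unique(fp[, "z"]) >=
                    scene@mixingLayerZ[1] - scene@wormZThickness / 2 - 1e-9))
  expect_true(all(unique(fp[, "z"]) <=
                    scene@mixingLayerZ[2] + scene@wormZThickness / 2 + 1e-9))
})

test_that("the time-course fixture shows the knock-down end to end", {
  hits <- 0L
  for (seed in 61:64) {
    outDir <- tempfile("tc")
    paths <- makeFixtureSuite(outDir, seed = seed)
    mu <- vapply(paths[paste0("timecourse_", c("0h", "2h", "24h"))],
                 function(p) {
                   totalBiospeckleIntensity(runSample(p)$result)
                 }, numeric(1))
    pct <- 100 * mu / mu[1]
    if (pct[3] < pct[2]) hits <- hits + 1L
    unlink(outDir, recursive = TRUE)
  }
  expect_gte(hits, 3)
})

test_that("a sample of five active worms yields a handful of objects with mu > 0", {
  for (seed in 71:73) {
    scan <- simulateScan(sceneSpec(), seed = seed)   # 5 active worms
    res <- summarizeSample(pipelineVolume(scan), sampleId = "mc")
    n <- length(detectedObjects(res))
    expect_gte(n, 1)
    expect_lte(n, 5)          # worms may touch and merge
    expect_gt(totalBiospeckleIntensity(res), 0)
  }
})

test_that("the fixture suite writes readable manifests incl. a time course", {
  outDir <- tempfile("fixtures")
  paths <- makeFixtureSuite(outDir, seed = 5)
  expect_gte(length(paths), 4)
  for (p in paths) {
    m <- readScanManifest(p)
    expect_s4_class(m, "ScanManifest")
  }
  tc <- paths[grepl("timecourse", names(paths))]
  expect_length(tc, 3)
  tps <- vapply(tc, function(p) readScanManifest(p)@timePointH, numeric(1))
  expect_setequal(tps, c(0, 2, 24))

  # determinism of fixture bytes
  outDir2 <- tempfile("fixtures2")
  paths2 <- makeFixtureSuite(outDir2, seed = 5)
  f1 <- file.path(dirname(paths[["active"]]), "step000", "frame000.tif")
  f2 <- file.path(dirname(paths2[["active"]]), "step000", "frame000.tif")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
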