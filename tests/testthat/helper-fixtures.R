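# Shared fixture builders. Everything is generated in code at test time.

makeStack <- function(arr, step = 0L) {
  new("FrameStack", frames = arr, stepIndex = as.integer(step),
      bitDepth = 8L)
}

makeVolume <- function(arr, voxel = c(x = 25, y = 25, z = 62.5)) {
  new("ActivityVolume", voxels = arr, voxelSizeUm = voxel)
}

makeArea <- function(px, intensities = rep(1, nrow(px)), plane = "XY",
                     vScale = 1) {
  new("BiospeckleArea", plane = plane,
      pixels = cbind(u = as.integer(px[, 1]), v = as.integer(px[, 2])),
      intensities = intensities, vScale = vScale)
}

# Full in-memory processing chain for simulated scans (the on-disk path
# through manifests is exercised separately in the scan IO / CLI tests).
pipelineVolume <- function(scan, config = bspimConfig()) {
  maps <- lapply(scan$stacks, generalizedDifferences,
                 normalization = config$normalization)
  vol <- stackMaps(maps, scan$scene@pixelSizeUm, scan$scene@stepSizeUm)
  if (!is.null(config$roi)) vol <- cropRoi(vol, config$roi)
  vol <- subtractBackground(vol, config$background_radius_mm,
                            scan$scene@pixelSizeUm)
  vol <- medianFilterVolume(vol, config$median_radius_px)
  gaussianBlur3d(vol, config$gaussian_sigma_vox)
}

# Scene used by the worm-resolving shape comparisons: one worm in a field
# wide enough that a motile trace does not reach the walls.
shapeScene <- function() {
  sceneSpec(nWorms = 1L, width = 96L, height = 96L, depth = 8L,
            mixingLayerZ = c(2, 6))
}

# Scene used by the screening simulations: a wide field of view (50 um
# pixels, ~8 mm across) in which 5 worms stay resolved as separate
# objects, as in the cuvette assay.
screeningScene <- function() {
  sceneSpec(width = 160L, height = 160L, depth = 5L,
            mixingLayerZ = c(1, 4), framesPerStep = 8L, pixelSizeUm = 50)
}

fiveWorms <- function(factor = 1) {
  replicate(5, scaleWormActivity(wormPreset("bacterial_feeder"),
                                 factor, factor), simplify = FALSE)
}

deadWorm <- function() {
  wm <- wormPreset("bacterial_feeder")
  wm@activity <- 0
  wm@speedPxPerFrame <- 0
  attr(wm, "undulationRatePerFrame") <- 0
  wm
}

screeningMu <- function(factor, seed) {
  scan <- simulateScan(screeningScene(), fiveWorms(factor), seed)
  totalBiospeckleIntensity(detectObjects(pipelineVolume(scan)))
}

# Rasterized filled disk mask (pixel centres within radius of the centre).
diskMask <- function(radius, gridSize = 2 * radius + 32) {
  cc <- (gridSize - 1) / 2
  xy <- expand.grid(x = 0:(gridSize - 1), y = 0:(gridSize - 1))
  inside <- (xy$x - cc)^2 + (xy$y - cc)^2 <= radius^2
  cbind(xy$x[inside], xy$y[inside])
}
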