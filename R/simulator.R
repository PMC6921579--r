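# Synthetic BSPIM scans: worms with trophic-group-specific motion inside
# a mixing-layer z band, imaged as a stepwise scan with a burst of frames
# per step. The speckle model targets the statistical contract the
# pipeline measures, not physical diffraction: fully developed
# (exponential-intensity) static speckle for the background, and worm
# pixels whose speckle value is redrawn between frames with probability
# activity * decorrelationScale, so temporal decorrelation scales with the
# activity parameter. Moving body parts decorrelate regardless: pixels
# entering or leaving the body footprint change value by occupancy alone.
# A single seed determines the entire scan; draws occur in a fixed order
# (background, then per step and frame: worm updates then sensor noise).

#' Scene specification constructor
#'
#' Builds a \linkS4class{SceneSpec} with the assay's default conditions:
#' 5 worms suspended in a mixing-layer band of a 64 x 64 x 10 voxel
#' volume, 16 frames per step, 62.5 um stage steps and 25 um pixels, 8-bit
#' frames, fully developed static background speckle (mean 60, contrast
#' 0.5), Gaussian sensor noise (sd 2) and worm speckle of mean 130.
#'
#' @param nWorms,width,height,depth,mixingLayerZ,speckleGrainPx
#'   scene geometry; see \linkS4class{SceneSpec}.
#' @param backgroundMean,backgroundContrast,sensorNoiseSd,wormMean,
#'   decorrelationScale speckle statistics.
#' @param framesPerStep,pixelSizeUm,stepSizeUm,wormZThickness,bitDepth
#'   acquisition geometry.
#' @return a \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(nWorms = 5L, width = 64L, height = 64L, depth = 10L,
                      mixingLayerZ = NULL, speckleGrainPx = 1L,
                      backgroundMean = 60, backgroundContrast = 0.5,
                      sensorNoiseSd = 2, wormMean = 130,
                      decorrelationScale = 0.2, framesPerStep = 16L,
                      pixelSizeUm = 25, stepSizeUm = 62.5,
                      wormZThickness = 2.5, bitDepth = 8L) {
  # worms sit in the central band of the column (the mixing layer);
  # for the default 10-step scan this is slices 3 to 7
  if (is.null(mixingLayerZ))
    mixingLayerZ <- c(0.3, 0.7) * depth
  new("SceneSpec", nWorms = as.integer(nWorms), width = as.integer(width),
      height = as.integer(height), depth = as.integer(depth),
      mixingLayerZ = as.numeric(mixingLayerZ),
      speckleGrainPx = as.integer(speckleGrainPx),
      backgroundMean = backgroundMean,
      backgroundContrast = backgroundContrast,
      sensorNoiseSd = sensorNoiseSd, wormMean = wormMean,
      decorrelationScale = decorrelationScale,
      framesPerStep = as.integer(framesPerStep),
      pixelSizeUm = pixelSizeUm, stepSizeUm = stepSizeUm,
      wormZThickness = wormZThickness, bitDepth = as.integer(bitDepth))
}

#' Worm specification constructor and trophic-group presets
#'
#' \code{wormPreset} returns the default \linkS4class{WormSpec} of a
#' trophic group. Bacterial feeders undulate smoothly with a long
#' wavelength, low amplitude and an oscillating head region; plant
#' feeders move sporadically (a two-state move/pause chain) with a short
#' wavelength, high amplitude and no head oscillation; Trichodorus worms
#' are alive but nearly stationary (activity > 0, speed ~ 0).
#'
#' @param group one of \code{"bacterial_feeder"}, \code{"plant_feeder"},
#'   \code{"trichodorus"}.
#' @return a \linkS4class{WormSpec}.
#' @examples
#' wormPreset("trichodorus")
#' @export
wormPreset <- function(group = c("bacterial_feeder", "plant_feeder",
                                 "trichodorus")) {
  group <- match.arg(group)
  p <- switch(group,
    bacterial_feeder = list(L = 30, wdt = 3, lam = 0.8, amp = 2,
                            ho = TRUE, hoAmp = 2, speed = 0.3, a = 0.9,
                            spor = FALSE, pStart = 0, pStop = 0,
                            rate = 0.5),
    plant_feeder = list(L = 30, wdt = 3, lam = 0.4, amp = 5,
                        ho = FALSE, hoAmp = 0, speed = 0.25, a = 0.7,
                        spor = TRUE, pStart = 0.08, pStop = 0.15,
                        rate = 0.3),
    trichodorus = list(L = 20, wdt = 3, lam = 1.0, amp = 6,
                       ho = FALSE, hoAmp = 0, speed = 0.02, a = 0.75,
                       spor = FALSE, pStart = 0, pStop = 0, rate = 0.01))
  wormSpec(group = group, bodyLengthPx = p$L, bodyWidthPx = p$wdt,
           undulationWavelength = p$lam, undulationAmplitudePx = p$amp,
           headOscillation = p$ho, headOscillationAmplitudePx = p$hoAmp,
           speedPxPerFrame = p$speed, activity = p$a, sporadic = p$spor,
           moveStartProb = p$pStart, moveStopProb = p$pStop,
           undulationRatePerFrame = p$rate)
}

#' @rdname wormPreset
#' @param bodyLengthPx,bodyWidthPx,undulationWavelength,
#'   undulationAmplitudePx,headOscillation,headOscillationAmplitudePx,
#'   speedPxPerFrame,activity,sporadic,moveStartProb,moveStopProb worm
#'   parameters; see \linkS4class{WormSpec}.
#' @param undulationRatePerFrame body-wave phase advance in radians per
#'   frame (attached as metadata on the spec).
#' @param position,zCenter,heading start pose; NA = placed automatically.
#' @export
wormSpec <- function(group = "other", bodyLengthPx = 30, bodyWidthPx = 3,
                     undulationWavelength = 0.6,
                     undulationAmplitudePx = 2, headOscillation = FALSE,
                     headOscillationAmplitudePx = 0,
                     speedPxPerFrame = 0.3, activity = 0.8,
                     sporadic = FALSE, moveStartProb = 0.1,
                     moveStopProb = 0.1, undulationRatePerFrame = 0.4,
                     position = c(NA_real_, NA_real_),
                     zCenter = NA_real_, heading = NA_real_) {
  obj <- new("WormSpec", group = group, bodyLengthPx = bodyLengthPx,
             bodyWidthPx = bodyWidthPx,
             undulationWavelength = undulationWavelength,
             undulationAmplitudePx = undulationAmplitudePx,
             headOscillation = headOscillation,
             headOscillationAmplitudePx = headOscillationAmplitudePx,
             speedPxPerFrame = speedPxPerFrame, activity = activity,
             sporadic = sporadic, moveStartProb = moveStartProb,
             moveStopProb = moveStopProb, position = as.numeric(position),
             zCenter = zCenter, heading = heading)
  attr(obj, "undulationRatePerFrame") <- undulationRatePerFrame
  obj
}

#' Scale a worm's bioactivity
#'
#' Multiplies activity and translation speed (with the undulation rate and
#' head-oscillation amplitude following the speed), the simulator's model
#' of a toxin-induced knock-down. Toxins typically suppress motility
#' faster than internal activity, so the two factors can differ.
#'
#' @param worm a \linkS4class{WormSpec}.
#' @param factor activity multiplier in [0, 1].
#' @param speedFactor motility multiplier in [0, 1]; defaults to
#'   \code{factor}.
#' @return the modified \linkS4class{WormSpec}.
#' @export
scaleWormActivity <- function(worm, factor, speedFactor = factor) {
  stopifnot(is(worm, "WormSpec"), factor >= 0, factor <= 1,
            speedFactor >= 0, speedFactor <= 1)
  rate <- attr(worm, "undulationRatePerFrame") %||% 0.4
  worm@activity <- worm@activity * factor
  worm@speedPxPerFrame <- worm@speedPxPerFrame * speedFactor
  worm@headOscillationAmplitudePx <-
    worm@headOscillationAmplitudePx * speedFactor
  attr(worm, "undulationRatePerFrame") <- rate * speedFactor
  worm
}

# Fully developed speckle field: iid unit-mean exponential intensities,
# optionally with a grain size > 1 px (block replication).
speckleField <- function(h, w, grain = 1L) {
  if (grain <= 1L) return(matrix(stats::rexp(h * w), h, w))
  hc <- ceiling(h / grain); wc <- ceiling(w / grain)
  coarse <- matrix(stats::rexp(hc * wc), hc, wc)
  coarse[rep(seq_len(hc), each = grain)[seq_len(h)],
         rep(seq_len(wc), each = grain)[seq_len(w)]]
}

# Fill in missing start poses; error if a given pose is outside the volume.
placeWorms <- function(worms, scene) {
  nw <- length(worms)
  ncols <- ceiling(sqrt(nw))
  nrows <- ceiling(nw / ncols)
  margin <- max(vapply(worms, function(wm) wm@bodyLengthPx, numeric(1))) / 3
  gx <- seq(margin, scene@width - 1 - margin, length.out = max(ncols, 2))
  gy <- seq(margin, scene@height - 1 - margin, length.out = max(nrows, 2))
  k <- 0L
  for (i in seq_len(nw)) {
    wm <- worms[[i]]
    if (any(is.na(wm@position))) {
      k <- k + 1L
      wm@position <- c(gx[((k - 1L) %% ncols) + 1L],
                       gy[((k - 1L) %/% ncols) + 1L]) +
                     stats::runif(2, -2, 2)
    }
    if (wm@position[1] < 0 || wm@position[1] > scene@width - 1 ||
        wm@position[2] < 0 || wm@position[2] > scene@height - 1)
      stop("worm ", i, " initialized outside the volume")
    if (is.na(wm@zCenter))
      wm@zCenter <- stats::runif(1, scene@mixingLayerZ[1],
                                 scene@mixingLayerZ[2])
    if (wm@zCenter < 0 || wm@zCenter >= scene@depth)
      stop("worm ", i, " initialized outside the volume (z)")
    if (is.na(wm@heading)) wm@heading <- stats::runif(1, 0, 2 * pi)
    worms[[i]] <- wm
  }
  worms
}

# Disc stamp offsets for the body cross-section.
discOffsets <- function(radius) {
  r <- max(0L, as.integer(floor(radius)))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 <= r^2 + 0.5, , drop = FALSE])
}

# Rasterize one worm posture into linear pixel indices of an h x w image.
rasterizeWorm <- function(pos, dir, phase, headPhase, wm, h, w, offs) {
  L <- wm@bodyLengthPx
  s <- seq(0, L, by = 0.5)
  nrm <- c(-dir[2], dir[1])
  off <- wm@undulationAmplitudePx *
    sin(2 * pi * s / (wm@undulationWavelength * L) + phase)
  if (wm@headOscillation)
    off <- off + wm@headOscillationAmplitudePx * sin(headPhase) *
      pmax(0, (s / L - 0.7) / 0.3)
  cx <- round(pos[1] + dir[1] * (s - L / 2) + nrm[1] * off)
  cy <- round(pos[2] + dir[2] * (s - L / 2) + nrm[2] * off)
  xx <- rep(cx, each = nrow(offs)) + offs[, "dx"]
  yy <- rep(cy, each = nrow(offs)) + offs[, "dy"]
  ok <- xx >= 0 & xx < w & yy >= 0 & yy < h
  unique((yy[ok] + 1L) + h * xx[ok])
}

# Reflect a coordinate into [lo, hi], returning the coordinate and a
# direction sign flip.
reflect1 <- function(x, lo, hi) {
  flip <- 1
  if (x < lo) { x <- 2 * lo - x; flip <- -1 }
  if (x > hi) { x <- 2 * hi - x; flip <- -1 }
  c(x, flip)
}

#' Simulate one BSPIM scan
#'
#' Generates the frame bursts of a full stage scan of a synthetic sample,
#' together with per-frame ground truth. Identical seeds give
#' byte-identical output.
#'
#' @param scene a \linkS4class{SceneSpec}.
#' @param worms list of \linkS4class{WormSpec}; NULL places
#'   \code{scene@nWorms} bacterial-feeder presets automatically.
#' @param seed integer random seed determining the whole scan.
#' @return list with elements \code{stacks} (list of
#'   \linkS4class{FrameStack}, one per step), \code{scene}, \code{worms}
#'   (with resolved start poses), \code{groundTruth} (list: \code{track}
#'   data.frame of per-frame worm poses; \code{footprints} list of
#'   per-worm 0-based voxel matrices x, y, z) and \code{seed}.
#' @export
simulateScan <- function(scene = sceneSpec(), worms = NULL, seed = 1L) {
  stopifnot(is(scene, "SceneSpec"))
  set.seed(as.integer(seed))
  h <- scene@height; w <- scene@width; dp <- scene@depth
  nT <- scene@framesPerStep
  if (is.null(worms))
    worms <- replicate(scene@nWorms, wormPreset("bacterial_feeder"),
                       simplify = FALSE)
  worms <- placeWorms(worms, scene)
  nw <- length(worms)
  maxGrey <- 2^scene@bitDepth - 1

  bg <- array(0, dim = c(h, w, dp))
  for (z in seq_len(dp))
    bg[, , z] <- scene@backgroundMean * (1 - scene@backgroundContrast) +
      scene@backgroundMean * scene@backgroundContrast *
      speckleField(h, w, scene@speckleGrainPx)

  # mutable per-worm state; worms swim in 3D: a fraction of the speed
  # goes into drift along the stage axis (slice units), bouncing at the
  # mixing-layer boundaries
  st <- lapply(worms, function(wm) list(
    pos = wm@position,
    dir = c(cos(wm@heading), sin(wm@heading)),
    zc = wm@zCenter,
    zdir = sample(c(-1, 1), 1),
    phase = 0, headPhase = 0,
    moving = !wm@sporadic && wm@speedPxPerFrame > 0,
    field = scene@wormMean * matrix(stats::rexp(h * w), h, w),
    prevMask = integer(0),
    rate = attr(wm, "undulationRatePerFrame") %||% 0.4))
  zDriftPerPx <- 0.15   # slices of z drift per pixel of swimming speed
  offs <- lapply(worms, function(wm) discOffsets(wm@bodyWidthPx / 2))
  footprints <- replicate(nw, integer(0), simplify = FALSE)
  margin <- vapply(worms, function(wm)
    min(wm@bodyLengthPx / 3 + wm@undulationAmplitudePx,
        (min(w, h) - 1) / 2), numeric(1))

  stacks <- vector("list", dp)
  nRec <- dp * nT * nw
  trWorm <- integer(nRec); trStep <- integer(nRec); trFrame <- integer(nRec)
  trX <- numeric(nRec); trY <- numeric(nRec); trZ <- numeric(nRec)
  trMoving <- logical(nRec); trInSlice <- logical(nRec)
  ti <- 0L
  for (z in 0:(dp - 1)) {
    arr <- array(0, dim = c(h, w, nT))
    for (t in seq_len(nT)) {
      frame <- bg[, , z + 1]
      for (i in seq_len(nw)) {
        wm <- worms[[i]]
        # move/pause switching for sporadic movers
        if (wm@sporadic) {
          u <- stats::runif(1)
          st[[i]]$moving <- if (st[[i]]$moving) u >= wm@moveStopProb else
            u < wm@moveStartProb
        }
        if (st[[i]]$moving && wm@speedPxPerFrame > 0) {
          p <- st[[i]]$pos + wm@speedPxPerFrame * st[[i]]$dir
          rx <- reflect1(p[1], margin[i], w - 1 - margin[i])
          ry <- reflect1(p[2], margin[i], h - 1 - margin[i])
          st[[i]]$pos <- c(rx[1], ry[1])
          st[[i]]$dir <- st[[i]]$dir * c(rx[2], ry[2])
          zr <- reflect1(st[[i]]$zc + wm@speedPxPerFrame * zDriftPerPx *
                           st[[i]]$zdir,
                         scene@mixingLayerZ[1],
                         min(scene@mixingLayerZ[2], scene@depth - 0.01))
          st[[i]]$zc <- zr[1]
          st[[i]]$zdir <- st[[i]]$zdir * zr[2]
          st[[i]]$phase <- st[[i]]$phase + st[[i]]$rate
        } else if (!wm@sporadic) {
          st[[i]]$phase <- st[[i]]$phase + st[[i]]$rate
        }
        # head oscillation is active motion: it stops in dead worms
        if (wm@headOscillation && wm@activity > 0)
          st[[i]]$headPhase <- st[[i]]$headPhase + 0.8
        inSlice <- abs(st[[i]]$zc - z) <= scene@wormZThickness / 2
        if (inSlice) {
          mask <- rasterizeWorm(st[[i]]$pos, st[[i]]$dir, st[[i]]$phase,
                                st[[i]]$headPhase, wm, h, w, offs[[i]])
          fresh <- setdiff(mask, st[[i]]$prevMask)
          if (length(fresh))
            st[[i]]$field[fresh] <- scene@wormMean *
              stats::rexp(length(fresh))
          p <- wm@activity * scene@decorrelationScale
          if (p > 0 && length(mask)) {
            redo <- mask[stats::runif(length(mask)) < p]
            if (length(redo))
              st[[i]]$field[redo] <- scene@wormMean *
                stats::rexp(length(redo))
          }
          frame[mask] <- st[[i]]$field[mask]
          st[[i]]$prevMask <- mask
          footprints[[i]] <- c(footprints[[i]], mask + h * w * z)
        }
        ti <- ti + 1L
        trWorm[ti] <- i; trStep[ti] <- z; trFrame[ti] <- t - 1L
        trX[ti] <- st[[i]]$pos[1]; trY[ti] <- st[[i]]$pos[2]
        trZ[ti] <- st[[i]]$zc
        trMoving[ti] <- st[[i]]$moving; trInSlice[ti] <- inSlice
      }
      frame <- frame + stats::rnorm(h * w, 0, scene@sensorNoiseSd)
      arr[, , t] <- pmin(pmax(round(frame), 0), maxGrey)
    }
    stacks[[z + 1]] <- new("FrameStack", frames = arr,
                           stepIndex = as.integer(z),
                           bitDepth = scene@bitDepth)
  }
  fp <- lapply(footprints, function(v) {
    v <- sort(unique(v))
    lin0 <- v - 1L
    zz <- lin0 %/% (h * w)
    rem <- lin0 %% (h * w)
    cbind(x = rem %/% h, y = rem %% h, z = zz)
  })
  track <- data.frame(worm = trWorm, step = trStep, frame = trFrame,
                      x = trX, y = trY, z = trZ, moving = trMoving,
                      in_slice = trInSlice)
  list(stacks = stacks, scene = scene, worms = worms,
       groundTruth = list(track = track, footprints = fp),
       seed = as.integer(seed))
}

#' Write a suite of small synthetic fixtures
#'
#' Writes ready-to-run scan manifests covering the test scenarios: an
#' active sample, a dead sample (activity and speed zero), a mixed
#' trophic-group sample, and a 3-time-point treatment series in which
#' worm activity declines between the pre-treatment and 24 h scans.
#'
#' @param outDir output directory.
#' @param seed integer seed; each fixture derives its own sub-seed.
#' @param scene a \linkS4class{SceneSpec} shared by the fixtures; the
#'   default is a fast desk-scale scene with a field of view wide enough
#'   (50 um pixels) that the 5 worms stay resolved as separate objects,
#'   as in the cuvette assay.
#' @return named character vector of manifest paths.
#' @export
makeFixtureSuite <- function(outDir, seed = 1L,
                             scene = sceneSpec(width = 160L, height = 160L,
                                               depth = 5L,
                                               mixingLayerZ = c(1, 4),
                                               framesPerStep = 8L,
                                               pixelSizeUm = 50)) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  paths <- c()
  bact <- function() wormPreset("bacterial_feeder")
  scanTo <- function(name, worms, sub, timePointH = 0,
                     treatment = "control", group = "bacterial_feeder",
                     sampleId = name) {
    sc <- simulateScan(scene, worms, seed * 1000L + sub)
    writeScan(sc, file.path(outDir, name), sampleId = sampleId,
              timePointH = timePointH, treatment = treatment,
              group = group)
  }
  paths["active"] <- scanTo("active", replicate(5, bact(),
                                                simplify = FALSE), 1L)
  paths["dead"] <- scanTo("dead", replicate(5, {
    wm <- bact(); wm@activity <- 0; wm@speedPxPerFrame <- 0
    attr(wm, "undulationRatePerFrame") <- 0; wm
  }, simplify = FALSE), 2L)
  paths["mixed"] <- scanTo("mixed", list(bact(), bact(),
                                         wormPreset("plant_feeder"),
                                         wormPreset("plant_feeder"),
                                         wormPreset("trichodorus")), 3L,
                           group = "other", sampleId = "mixed")
  tcWorms <- function(f) replicate(5, scaleWormActivity(bact(), f),
                                   simplify = FALSE)
  paths["timecourse_0h"] <- scanTo("timecourse_0h", tcWorms(1), 4L,
                                   timePointH = 0, treatment = "PEITC",
                                   sampleId = "treated")
  paths["timecourse_2h"] <- scanTo("timecourse_2h", tcWorms(0.9), 5L,
                                   timePointH = 2, treatment = "PEITC",
                                   sampleId = "treated")
  paths["timecourse_24h"] <- scanTo("timecourse_24h", tcWorms(0.35), 6L,
                                    timePointH = 24, treatment = "PEITC",
                                    sampleId = "treated")
  paths
}
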