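#' @import methods
NULL

#' Scan manifest
#'
#' Describes one BSPIM scan of a sample: an ordered series of stage steps,
#' each holding a burst of brightfield frames, together with the physical
#' geometry of the acquisition (in-plane pixel size, stage step increment)
#' and the screening metadata (time point, treatment, trophic group).
#'
#' @slot sampleId character scalar identifying the sample.
#' @slot steps list of step records; each is a list with elements
#'   \code{index} (integer, 0-based stage step) and \code{frames}
#'   (character vector of frame file paths, relative to \code{baseDir}).
#' @slot framesPerStep integer, number of frames T captured per step.
#' @slot stepSizeUm numeric, stage increment between steps in micrometres.
#' @slot pixelSizeUm numeric, in-plane pixel size in micrometres.
#' @slot bitDepth integer, camera bit depth of the stored frames.
#' @slot timePointH numeric, hours since treatment (0 = pre-treatment).
#' @slot treatment character treatment label (e.g. control, PEITC, methanol).
#' @slot group character trophic-group label (bacterial_feeder,
#'   plant_feeder, trichodorus, other).
#' @slot baseDir character directory against which frame paths resolve.
#' @export
setClass("ScanManifest",
  representation(
    sampleId = "character",
    steps = "list",
    framesPerStep = "integer",
    stepSizeUm = "numeric",
    pixelSizeUm = "numeric",
    bitDepth = "integer",
    timePointH = "numeric",
    treatment = "character",
    group = "character",
    baseDir = "character"
  )
)

setValidity("ScanManifest", function(object) {
  msg <- character(0)
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@steps) < 1L)
    msg <- c(msg, "manifest must contain at least one step")
  if (length(object@framesPerStep) != 1L || object@framesPerStep < 2L)
    msg <- c(msg, "frames_per_step must be at least 2")
  if (object@stepSizeUm <= 0)
    msg <- c(msg, "step_size_um must be positive")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixel_size_um must be positive")
  if (length(object@steps) >= 1L) {
    idx <- vapply(object@steps, function(s) as.integer(s$index), integer(1))
    if (any(diff(idx) <= 0))
      msg <- c(msg, "step indices must be strictly increasing")
    nf <- vapply(object@steps, function(s) length(s$frames), integer(1))
    bad <- which(nf != object@framesPerStep)
    if (length(bad))
      msg <- c(msg, sprintf(
        "step %d has %d frame(s), expected frames_per_step = %d",
        idx[bad[1]], nf[bad[1]], object@framesPerStep))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScanManifest", function(object) {
  cat(sprintf(
    "ScanManifest '%s': %d step(s) x %d frames, step %.3g um, pixel %.3g um\n",
    object@sampleId, length(object@steps), object@framesPerStep,
    object@stepSizeUm, object@pixelSizeUm))
  cat(sprintf("  time %g h | treatment '%s' | group '%s'\n",
    object@timePointH, object@treatment, object@group))
})

#' Frame stack
#'
#' One burst of co-registered grayscale frames captured at a single stage
#' step. Frames are stored as an array indexed \code{[y, x, t]} (rows are
#' image height, columns image width), grey values are non-negative.
#'
#' @slot frames numeric array of dimension height x width x T.
#' @slot stepIndex integer 0-based stage step the burst belongs to.
#' @slot bitDepth integer camera bit depth.
#' @export
setClass("FrameStack",
  representation(frames = "array", stepIndex = "integer",
                 bitDepth = "integer")
)

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array [y, x, t]")
  if (d[3] < 2L) return("a frame stack needs at least 2 frames")
  if (any(object@frames < 0)) return("grey values must be >= 0")
  TRUE
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d x %d px, T = %d frames, step %d\n",
              d[2], d[1], d[3], object@stepIndex))
})

#' Activity map
#'
#' A single 2D map of biospeckle activity for one optical section, produced
#' by the generalized differences reduction of a \linkS4class{FrameStack}.
#'
#' @slot values numeric matrix (height x width) of non-negative activity
#'   grey values.
#' @slot stepIndex integer 0-based stage step.
#' @slot normalization character, \code{"mean_pair"} or \code{"sum"}.
#' @export
setClass("ActivityMap",
  representation(values = "matrix", stepIndex = "integer",
                 normalization = "character")
)

setValidity("ActivityMap", function(object) {
  if (any(object@values < 0)) return("activity values must be >= 0")
  if (!object@normalization %in% c("mean_pair", "sum"))
    return("normalization must be 'mean_pair' or 'sum'")
  TRUE
})

setMethod("show", "ActivityMap", function(object) {
  cat(sprintf("ActivityMap: %d x %d px, step %d, normalization '%s'\n",
              ncol(object@values), nrow(object@values), object@stepIndex,
              object@normalization))
})

#' Activity volume
#'
#' The 3D voxel grid of biospeckle activity obtained by stacking per-step
#' activity maps along the stage axis. Voxels are stored \code{[y, x, z]};
#' the physical voxel size is anisotropic (z is the stage step increment)
#' and carried as metadata, never resampled.
#'
#' @slot voxels numeric array height x width x depth of non-negative grey
#'   values.
#' @slot voxelSizeUm named numeric vector \code{c(x=, y=, z=)} of physical
#'   voxel sizes in micrometres.
#' @export
setClass("ActivityVolume",
  representation(voxels = "array", voxelSizeUm = "numeric")
)

setValidity("ActivityVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array [y, x, z]")
  if (any(object@voxels < 0)) return("voxel values must be >= 0")
  if (length(object@voxelSizeUm) != 3L || any(object@voxelSizeUm <= 0))
    return("voxelSizeUm must be 3 positive values (x, y, z)")
  TRUE
})

setMethod("show", "ActivityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "ActivityVolume: %d x %d x %d voxels (%.3g x %.3g x %.3g um)\n",
    d[2], d[1], d[3],
    object@voxelSizeUm[["x"]], object@voxelSizeUm[["y"]],
    object@voxelSizeUm[["z"]]))
})

#' Detected biospeckle object
#'
#' A connected set of voxels above the detection threshold, with the
#' standard descriptors: biospeckle volume (voxel count) and biospeckle
#' intensity (mean grey value). Coordinates are 0-based with x along image
#' width, y along image height and z along the stage axis.
#'
#' @slot label integer deterministic object label (raster order of the
#'   object's minimum voxel index).
#' @slot voxels integer matrix with columns x, y, z (0-based).
#' @slot nVoxels integer biospeckle volume N.
#' @slot meanIntensity numeric biospeckle intensity I (mean grey value).
#' @slot centroid numeric length-3 centroid (x, y, z), 0-based.
#' @slot bbox integer length-6 bounding box (x0, y0, z0, x1, y1, z1),
#'   half-open on the upper bound.
#' @export
setClass("DetectedObject",
  representation(label = "integer", voxels = "matrix", nVoxels = "integer",
                 meanIntensity = "numeric", centroid = "numeric",
                 bbox = "integer")
)

setValidity("DetectedObject", function(object) {
  if (object@nVoxels != nrow(object@voxels))
    return("nVoxels must equal the number of voxel rows")
  if (ncol(object@voxels) != 3L)
    return("voxels must have columns x, y, z")
  TRUE
})

setMethod("show", "DetectedObject", function(object) {
  cat(sprintf("DetectedObject #%d: N = %d voxels, I = %.2f, centroid (%.1f, %.1f, %.1f)\n",
              object@label, object@nVoxels, object@meanIntensity,
              object@centroid[1], object@centroid[2], object@centroid[3]))
})

#' Per-sample detection result
#'
#' All biospeckle objects detected in one scan plus the sample-level
#' readout: the total biospeckle intensity, i.e. the sum of per-object mean
#' intensities.
#'
#' @slot sampleId character sample identifier.
#' @slot objects list of \linkS4class{DetectedObject}.
#' @slot totalIntensity numeric total biospeckle intensity (sum of object
#'   mean intensities; 0 when nothing was detected).
#' @slot timePointH numeric hours since treatment.
#' @slot treatment character treatment label.
#' @slot group character trophic-group label.
#' @slot parameters list of the detection parameters used.
#' @export
setClass("SampleResult",
  representation(sampleId = "character", objects = "list",
                 totalIntensity = "numeric", timePointH = "numeric",
                 treatment = "character", group = "character",
                 parameters = "list")
)

setValidity("SampleResult", function(object) {
  mu <- sum(vapply(object@objects, function(o) o@meanIntensity, numeric(1)))
  if (length(object@objects) == 0 && object@totalIntensity != 0)
    return("totalIntensity must be 0 when no objects were detected")
  if (length(object@objects) > 0 &&
      abs(object@totalIntensity - mu) > 1e-8 * max(1, abs(mu)))
    return("totalIntensity must equal the sum of object mean intensities")
  TRUE
})

setMethod("show", "SampleResult", function(object) {
  cat(sprintf(
    "SampleResult '%s': %d object(s), total biospeckle intensity = %.2f\n",
    object@sampleId, length(object@objects), object@totalIntensity))
  cat(sprintf("  time %g h | treatment '%s' | group '%s'\n",
              object@timePointH, object@treatment, object@group))
})

#' Projected biospeckle area
#'
#' The 2D projection of a detected object onto the XY plane (facing the
#' objective) or the YZ plane (perpendicular to the light sheet): the set
#' of pixels hit by at least one object voxel along the collapsed axis,
#' with maximum-intensity grey values. For the YZ plane the z axis is
#' rescaled to physical aspect before hull fitting; \code{vScale} records
#' that factor.
#'
#' @slot plane character, \code{"XY"} or \code{"YZ"}.
#' @slot pixels integer matrix with columns u, v (0-based projected
#'   coordinates; u = x, v = y for XY; u = y, v = z for YZ).
#' @slot intensities numeric per-pixel maximum grey value along the
#'   collapsed axis.
#' @slot vScale numeric scale applied to the v axis before hull fitting.
#' @export
setClass("BiospeckleArea",
  representation(plane = "character", pixels = "matrix",
                 intensities = "numeric", vScale = "numeric")
)

setValidity("BiospeckleArea", function(object) {
  if (!object@plane %in% c("XY", "YZ")) return("plane must be 'XY' or 'YZ'")
  if (nrow(object@pixels) < 1L) return("projected mask must be non-empty")
  if (nrow(object@pixels) != length(object@intensities))
    return("one intensity per projected pixel required")
  if (object@vScale <= 0) return("vScale must be positive")
  TRUE
})

setMethod("show", "BiospeckleArea", function(object) {
  cat(sprintf("BiospeckleArea (%s): %d pixel(s), v-scale %.3g\n",
              object@plane, nrow(object@pixels), object@vScale))
})

#' Shape descriptor of a projected biospeckle area
#'
#' Convex-hull shape descriptors of one projection: hull area S, hull
#' perimeter P, circularity 4*pi*S/P^2 and the integrated density (sum of
#' projected grey values over the mask).
#'
#' @slot plane character projection plane.
#' @slot hullVertices numeric matrix of hull vertex coordinates (u, v in
#'   physical-aspect units).
#' @slot hullArea numeric hull area S.
#' @slot hullPerimeter numeric hull perimeter P.
#' @slot circularity numeric 4*pi*S/P^2.
#' @slot integratedDensity numeric sum of projected grey values.
#' @export
setClass("ShapeDescriptor",
  representation(plane = "character", hullVertices = "matrix",
                 hullArea = "numeric", hullPerimeter = "numeric",
                 circularity = "numeric", integratedDensity = "numeric")
)

setValidity("ShapeDescriptor", function(object) {
  if (object@hullArea <= 0) return("hull area must be positive")
  if (object@hullPerimeter <= 0) return("hull perimeter must be positive")
  if (object@circularity <= 0) return("circularity must be positive")
  TRUE
})

setMethod("show", "ShapeDescriptor", function(object) {
  cat(sprintf(
    "ShapeDescriptor (%s): S = %.2f, P = %.2f, circularity = %.3f, IntDen = %.1f\n",
    object@plane, object@hullArea, object@hullPerimeter,
    object@circularity, object@integratedDensity))
})

#' Synthetic worm specification
#'
#' Parameters of one simulated nematode: body geometry, undulation pattern,
#' translation speed, two-state (move/pause) switching for sporadic movers,
#' and the activity parameter a in [0, 1] controlling frame-to-frame
#' speckle decorrelation (0 = dead).
#'
#' @slot group character trophic-group label.
#' @slot bodyLengthPx,bodyWidthPx numeric body geometry in pixels.
#' @slot undulationWavelength numeric wavelength as a fraction of body
#'   length.
#' @slot undulationAmplitudePx numeric transverse undulation amplitude.
#' @slot headOscillation logical whether the head region oscillates.
#' @slot headOscillationAmplitudePx numeric head oscillation amplitude.
#' @slot speedPxPerFrame numeric translation speed.
#' @slot activity numeric speckle decorrelation activity a in [0, 1].
#' @slot sporadic logical two-state move/pause behaviour.
#' @slot moveStartProb,moveStopProb numeric per-frame transition
#'   probabilities of the move/pause chain.
#' @slot position numeric length-2 start position (x, y) or NA for
#'   automatic placement.
#' @slot zCenter numeric start z (stage-slice units) or NA for automatic
#'   placement in the mixing layer.
#' @slot heading numeric start heading in radians or NA for random.
#' @export
setClass("WormSpec",
  representation(group = "character", bodyLengthPx = "numeric",
                 bodyWidthPx = "numeric", undulationWavelength = "numeric",
                 undulationAmplitudePx = "numeric",
                 headOscillation = "logical",
                 headOscillationAmplitudePx = "numeric",
                 speedPxPerFrame = "numeric", activity = "numeric",
                 sporadic = "logical", moveStartProb = "numeric",
                 moveStopProb = "numeric", position = "numeric",
                 zCenter = "numeric", heading = "numeric")
)

setValidity("WormSpec", function(object) {
  if (object@activity < 0 || object@activity > 1)
    return("activity must lie in [0, 1]")
  if (object@bodyLengthPx <= 0 || object@bodyWidthPx <= 0)
    return("body dimensions must be positive")
  if (object@speedPxPerFrame < 0) return("speed must be >= 0")
  TRUE
})

setMethod("show", "WormSpec", function(object) {
  cat(sprintf(
    "WormSpec (%s): L = %g px, speed = %g px/frame, activity = %g%s\n",
    object@group, object@bodyLengthPx, object@speedPxPerFrame,
    object@activity, if (object@sporadic) ", sporadic" else ""))
})

#' Synthetic scene specification
#'
#' The scan-level conditions of a simulated BSPIM acquisition: volume
#' geometry, the mixing-layer band where worms are suspended, background
#' speckle statistics, sensor noise and the per-step burst length.
#'
#' @slot nWorms integer number of worms per sample (the assay default is 5).
#' @slot width,height,depth integer volume dimensions in voxels.
#' @slot mixingLayerZ numeric length-2 z band (0-based, half-open) where
#'   worms are placed.
#' @slot speckleGrainPx integer speckle grain size in pixels.
#' @slot backgroundMean numeric mean background grey value.
#' @slot backgroundContrast numeric static speckle contrast in [0, 1].
#' @slot sensorNoiseSd numeric per-frame Gaussian sensor noise sd.
#' @slot wormMean numeric mean grey value of worm speckle.
#' @slot decorrelationScale numeric per-frame redraw probability at
#'   activity 1 (keeps a burst of T frames from saturating).
#' @slot framesPerStep integer burst length T.
#' @slot pixelSizeUm,stepSizeUm numeric physical geometry.
#' @slot wormZThickness numeric effective worm thickness in stage-step
#'   units (includes the light-sheet thickness).
#' @slot bitDepth integer camera bit depth.
#' @export
setClass("SceneSpec",
  representation(nWorms = "integer", width = "integer", height = "integer",
                 depth = "integer", mixingLayerZ = "numeric",
                 speckleGrainPx = "integer", backgroundMean = "numeric",
                 backgroundContrast = "numeric", sensorNoiseSd = "numeric",
                 wormMean = "numeric", decorrelationScale = "numeric",
                 framesPerStep = "integer", pixelSizeUm = "numeric",
                 stepSizeUm = "numeric", wormZThickness = "numeric",
                 bitDepth = "integer")
)

setValidity("SceneSpec", function(object) {
  if (object@nWorms < 0) return("nWorms must be >= 0")
  if (object@width < 8 || object@height < 8 || object@depth < 1)
    return("volume must be at least 8 x 8 x 1 voxels")
  if (object@framesPerStep < 2) return("framesPerStep must be >= 2")
  if (object@mixingLayerZ[1] < 0 || object@mixingLayerZ[2] > object@depth ||
      object@mixingLayerZ[1] >= object@mixingLayerZ[2])
    return("mixingLayerZ must be a non-empty band inside [0, depth]")
  if (object@backgroundContrast < 0 || object@backgroundContrast > 1)
    return("backgroundContrast must lie in [0, 1]")
  if (object@decorrelationScale <= 0 || object@decorrelationScale > 1)
    return("decorrelationScale must lie in (0, 1]")
  TRUE
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d x %d voxels, T = %d, %d worm(s), mixing layer z [%g, %g)\n",
    object@width, object@height, object@depth, object@framesPerStep,
    object@nWorms, object@mixingLayerZ[1], object@mixingLayerZ[2]))
})
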