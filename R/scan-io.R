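# Reading and writing scans: YAML manifests, TIFF frame bursts, CSV tables.
# Frames are stored on disk as integer TIFF (bit depth from the manifest)
# and normalised to numeric grey values in memory; filtering and the
# generalized differences produce non-integer values downstream.

#' Read a scan manifest
#'
#' Parses a YAML scan manifest, validates its geometry and frame counts,
#' and returns a \linkS4class{ScanManifest}. Frame data are not loaded;
#' use \code{\link{loadFrameStack}} to load one step's burst on demand.
#'
#' @param path path to the manifest YAML file. Frame paths inside the
#'   manifest are resolved relative to the manifest's directory.
#' @param checkFrames logical; verify that every referenced frame file
#'   exists (default TRUE).
#' @return a \linkS4class{ScanManifest}.
#' @seealso \code{\link{loadFrameStack}}, \code{\link{writeScan}}
#' @export
readScanManifest <- function(path, checkFrames = TRUE) {
  if (!file.exists(path))
    stop("manifest file not found: ", path)
  y <- yaml::read_yaml(path)
  required <- c("sample_id", "frames_per_step", "step_size_um",
                "pixel_size_um", "steps")
  missing <- setdiff(required, names(y))
  if (length(missing))
    stop("manifest ", path, " is missing field(s): ",
         paste(missing, collapse = ", "))
  if (length(y$steps) == 0)
    stop("manifest ", path, " declares no steps")
  steps <- lapply(y$steps, function(s) {
    if (is.null(s$index) || is.null(s$frames))
      stop("each manifest step needs 'index' and 'frames'")
    list(index = as.integer(s$index),
         frames = as.character(unlist(s$frames)))
  })
  m <- new("ScanManifest",
    sampleId = as.character(y$sample_id),
    steps = steps,
    framesPerStep = as.integer(y$frames_per_step),
    stepSizeUm = as.numeric(y$step_size_um),
    pixelSizeUm = as.numeric(y$pixel_size_um),
    bitDepth = as.integer(y$bit_depth %||% 8L),
    timePointH = as.numeric(y$time_point_h %||% 0),
    treatment = as.character(y$treatment %||% "control"),
    group = as.character(y$group %||% "other"),
    baseDir = dirname(normalizePath(path))
  )
  if (checkFrames) {
    for (s in m@steps) {
      fp <- file.path(m@baseDir, s$frames)
      ok <- file.exists(fp)
      if (!ok[1] || !all(ok))
        stop("frame file missing for step ", s$index, ": ",
             fp[which(!ok)[1]])
    }
  }
  bspimLog("scan_io", sprintf("read manifest with %d step(s)",
                              length(m@steps)), sampleId = m@sampleId)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load one step's frame burst
#'
#' Reads the TIFF frames of a single stage step into a
#' \linkS4class{FrameStack}. Grey values are returned on the integer
#' camera scale (0 .. 2^bitDepth - 1).
#'
#' @param manifest a \linkS4class{ScanManifest}.
#' @param step 0-based stage step index as recorded in the manifest.
#' @return a \linkS4class{FrameStack}.
#' @export
loadFrameStack <- function(manifest, step) {
  stopifnot(is(manifest, "ScanManifest"))
  idx <- vapply(manifest@steps, function(s) s$index, integer(1))
  k <- match(step, idx)
  if (is.na(k)) stop("manifest has no step with index ", step)
  paths <- file.path(manifest@baseDir, manifest@steps[[k]]$frames)
  scale <- 2^manifest@bitDepth - 1
  mats <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("frame file not found: ", p)
    round(tiff::readTIFF(p) * scale)
  })
  d1 <- dim(mats[[1]])
  same <- vapply(mats, function(m) identical(dim(m), d1), logical(1))
  if (!all(same))
    stop("inconsistent frame dimensions in step ", step)
  arr <- array(unlist(mats), dim = c(d1[1], d1[2], length(mats)))
  new("FrameStack", frames = arr, stepIndex = as.integer(step),
      bitDepth = manifest@bitDepth)
}

#' Write a simulated or loaded scan to disk
#'
#' Writes per-step TIFF frames plus a YAML manifest readable by
#' \code{\link{readScanManifest}}. If the scan carries ground truth (a
#' simulator output), the per-frame worm track is written as CSV next to
#' the manifest.
#'
#' @param scan a scan as returned by \code{\link{simulateScan}}, or a list
#'   with elements \code{stacks} (list of \linkS4class{FrameStack}) and
#'   \code{scene} (a \linkS4class{SceneSpec}).
#' @param dir output directory (created if needed).
#' @param sampleId sample identifier recorded in the manifest.
#' @param timePointH,treatment,group screening metadata.
#' @return the manifest path, invisibly.
#' @export
writeScan <- function(scan, dir, sampleId = "sample",
                      timePointH = 0, treatment = "control",
                      group = "bacterial_feeder") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scene <- scan$scene
  scale <- 2^scene@bitDepth - 1
  steps <- list()
  for (st in scan$stacks) {
    z <- st@stepIndex
    stepDir <- sprintf("step%03d", z)
    dir.create(file.path(dir, stepDir), showWarnings = FALSE)
    nT <- dim(st@frames)[3]
    fns <- character(nT)
    for (t in seq_len(nT)) {
      fn <- file.path(stepDir, sprintf("frame%03d.tif", t - 1L))
      tiff::writeTIFF(pmin(pmax(st@frames[, , t], 0), scale) / scale,
                      file.path(dir, fn),
                      bits.per.sample = scene@bitDepth)
      fns[t] <- fn
    }
    steps[[length(steps) + 1L]] <- list(index = z, frames = as.list(fns))
  }
  manifest <- list(
    sample_id = sampleId,
    frames_per_step = scene@framesPerStep,
    step_size_um = scene@stepSizeUm,
    pixel_size_um = scene@pixelSizeUm,
    bit_depth = scene@bitDepth,
    time_point_h = timePointH,
    treatment = treatment,
    group = group,
    steps = steps
  )
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  if (!is.null(scan$groundTruth$track))
    writeResults(scan$groundTruth$track,
                 file.path(dir, "ground_truth_track.csv"))
  bspimLog("scan_io", sprintf("wrote scan (%d steps) to %s",
                              length(steps), dir), sampleId = sampleId)
  invisible(mpath)
}

#' Write a result table as CSV
#'
#' Writes rows sharing a schema to a UTF-8 CSV with a header line and the
#' column order of the input, at full numeric precision.
#'
#' @param records a data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(records, path) {
  stopifnot(is.data.frame(records))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(format(records, digits = 17, scientific = FALSE,
                          trim = TRUE, justify = "none"),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a result table written by \code{writeResults}
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export an activity volume as a float TIFF stack
#'
#' Writes one 32-bit float TIFF per z slice. TIFF float samples are
#' stored in [0, 1], so voxel values are divided by \code{scale} (the
#' grey range by default); the scale and voxel sizes are recorded in a
#' \code{volume.yaml} sidecar next to the slices.
#'
#' @param volume an \linkS4class{ActivityVolume}.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param scale divisor applied before writing (default 255, the 8-bit
#'   grey range; generalized-differences values never exceed it).
#' @return character vector of written paths, invisibly.
#' @export
writeActivityVolume <- function(volume, dir, prefix = "activity",
                                scale = 255) {
  stopifnot(is(volume, "ActivityVolume"), scale > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume@voxels)
  paths <- character(d[3])
  for (z in seq_len(d[3])) {
    paths[z] <- file.path(dir, sprintf("%s_z%03d.tif", prefix, z - 1L))
    tiff::writeTIFF(pmin(volume@voxels[, , z] / scale, 1), paths[z],
                    bits.per.sample = 32, reduce = FALSE)
  }
  yaml::write_yaml(list(prefix = prefix, scale = scale, depth = d[3],
                        voxel_size_um = as.list(volume@voxelSizeUm)),
                   file.path(dir, "volume.yaml"))
  invisible(paths)
}
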