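# Object detection: strict grey-level thresholding, 3D connected
# components (26- or 6-connectivity) and the per-object descriptors:
# biospeckle volume N (voxel count) and biospeckle intensity I (mean grey
# value). Components are found by label-minimum propagation over the
# foreground adjacency; labels are assigned in raster order (x fastest,
# then y, then z) of each component's minimum voxel index, so outputs are
# byte-reproducible.

neighborOffsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  as.matrix(g)
}

#' Detect biospeckle objects in a filtered volume
#'
#' Voxels whose grey value strictly exceeds \code{threshold} form the
#' foreground; connected components under the chosen connectivity are
#' extracted and components with at least \code{minSize} voxels are
#' returned as \linkS4class{DetectedObject}s. An empty foreground returns
#' an empty list, not an error.
#'
#' @param volume an \linkS4class{ActivityVolume} (normally the output of
#'   \code{\link{processScan}}).
#' @param threshold grey-level detection threshold (strict; default 20).
#' @param minSize minimum voxel count of a retained object (inclusive;
#'   default 20).
#' @param connectivity 26 (default) or 6.
#' @return list of \linkS4class{DetectedObject}, labelled 1, 2, ... in
#'   raster order of their minimum voxel index.
#' @examples
#' arr <- array(0, c(8, 8, 4)); arr[2:4, 2:4, 2:4] <- 50
#' vol <- new("ActivityVolume", voxels = arr,
#'            voxelSizeUm = c(x = 25, y = 25, z = 62.5))
#' obj <- detectObjects(vol)
#' nVoxels(obj[[1]])          # 27
#' meanIntensity(obj[[1]])    # 50
#' @export
detectObjects <- function(volume, threshold = 20, minSize = 20,
                          connectivity = 26L) {
  stopifnot(is(volume, "ActivityVolume"))
  if (threshold < 0) stop("threshold must be >= 0")
  if (minSize < 1) stop("minimum object size must be >= 1")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  d <- dim(volume@voxels)          # [h, w, depth]
  h <- d[1]; w <- d[2]; dp <- d[3]
  fgLin <- which(volume@voxels > threshold)
  if (length(fgLin) == 0L) return(list())
  co <- arrayInd(fgLin, d)         # columns: y, x, z (1-based)
  y <- co[, 1]; x <- co[, 2]; z <- co[, 3]
  n <- length(fgLin)
  # raster index: 0-based, x fastest, then y, then z
  raster <- (x - 1) + w * (y - 1) + w * h * (z - 1)
  lookup <- integer(h * w * dp)
  lookup[fgLin] <- seq_len(n)
  offs <- neighborOffsets(connectivity)
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    xx <- x + offs[k, "dx"]; yy <- y + offs[k, "dy"]; zz <- z + offs[k, "dz"]
    ok <- xx >= 1L & xx <= w & yy >= 1L & yy <= h & zz >= 1L & zz <= dp
    lin <- yy[ok] + h * (xx[ok] - 1L) + h * w * (zz[ok] - 1L)
    pos <- lookup[lin]
    pos[pos == 0L] <- NA_integer_
    nb[ok, k] <- pos
  }
  lab <- as.numeric(raster)
  repeat {
    newLab <- lab
    for (k in seq_len(ncol(nb))) {
      v <- lab[nb[, k]]
      v[is.na(v)] <- Inf
      newLab <- pmin(newLab, v)
    }
    if (identical(newLab, lab)) break
    lab <- newLab
  }
  comp <- split(seq_len(n), lab)
  sizes <- lengths(comp)
  keep <- comp[sizes >= minSize]
  keep <- keep[order(as.numeric(names(keep)))]
  vals <- volume@voxels[fgLin]
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    members <- keep[[i]][order(raster[keep[[i]]])]
    vox <- cbind(x = x[members] - 1L, y = y[members] - 1L,
                 z = z[members] - 1L)
    out[[i]] <- new("DetectedObject",
      label = as.integer(i),
      voxels = vox,
      nVoxels = length(members),
      meanIntensity = mean(vals[members]),
      centroid = c(x = mean(vox[, 1]), y = mean(vox[, 2]),
                   z = mean(vox[, 3])),
      bbox = as.integer(c(min(vox[, 1]), min(vox[, 2]), min(vox[, 3]),
                          max(vox[, 1]) + 1L, max(vox[, 2]) + 1L,
                          max(vox[, 3]) + 1L)))
  }
  out
}

#' Total biospeckle intensity of a sample
#'
#' The sample-level bioactivity readout: the sum of the mean intensities
#' of all detected objects. An empty object list gives 0.
#'
#' @param objects list of \linkS4class{DetectedObject} (or a
#'   \linkS4class{SampleResult}).
#' @return numeric scalar.
#' @export
totalBiospeckleIntensity <- function(objects) {
  if (is(objects, "SampleResult")) objects <- objects@objects
  if (length(objects) == 0L) return(0)
  sum(vapply(objects, function(o) o@meanIntensity, numeric(1)))
}

#' Detect objects and summarise a sample
#'
#' Runs detection on a filtered volume and assembles a
#' \linkS4class{SampleResult} carrying the per-object descriptors, the
#' total biospeckle intensity and the detection parameters used.
#'
#' @param volume a filtered \linkS4class{ActivityVolume}.
#' @param config a \code{\link{bspimConfig}} list.
#' @param sampleId,timePointH,treatment,group sample metadata.
#' @return a \linkS4class{SampleResult}.
#' @export
summarizeSample <- function(volume, config = bspimConfig(),
                            sampleId = "sample", timePointH = 0,
                            treatment = "control", group = "other") {
  objs <- detectObjects(volume, config$intensity_threshold,
                        config$min_object_size, config$connectivity)
  bspimLog("detection", sprintf("%d object(s) detected", length(objs)),
           sampleId = sampleId)
  new("SampleResult",
      sampleId = sampleId, objects = objs,
      totalIntensity = totalBiospeckleIntensity(objs),
      timePointH = timePointH, treatment = treatment, group = group,
      parameters = list(intensity_threshold = config$intensity_threshold,
                        min_object_size = config$min_object_size,
                        connectivity = config$connectivity))
}

#' Per-object descriptor table
#'
#' Flattens a \linkS4class{SampleResult} into one row per detected object
#' (voxel count, mean intensity, centroid, bounding box) for CSV export.
#'
#' @param result a \linkS4class{SampleResult}.
#' @return a data.frame.
#' @export
objectTable <- function(result) {
  stopifnot(is(result, "SampleResult"))
  objs <- result@objects
  if (length(objs) == 0L) {
    return(data.frame(sample_id = character(0), label = integer(0),
                      n_voxels = integer(0), mean_intensity = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0), bbox_x0 = integer(0),
                      bbox_y0 = integer(0), bbox_z0 = integer(0),
                      bbox_x1 = integer(0), bbox_y1 = integer(0),
                      bbox_z1 = integer(0)))
  }
  do.call(rbind, lapply(objs, function(o) data.frame(
    sample_id = result@sampleId, label = o@label, n_voxels = o@nVoxels,
    mean_intensity = o@meanIntensity,
    centroid_x = o@centroid[[1]], centroid_y = o@centroid[[2]],
    centroid_z = o@centroid[[3]],
    bbox_x0 = o@bbox[1], bbox_y0 = o@bbox[2], bbox_z0 = o@bbox[3],
    bbox_x1 = o@bbox[4], bbox_y1 = o@bbox[5], bbox_z1 = o@bbox[6])))
}
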