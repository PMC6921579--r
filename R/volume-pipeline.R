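# Assembly of per-step activity maps into a 3D activity volume and the
# filtering chain applied before object detection. The stage order is
# fixed: crop -> background subtraction -> median -> 3D Gaussian.
# Voxels are anisotropic (z = stage step) and carried as metadata only.

#' Stack activity maps into a volume
#'
#' Stacks per-step activity maps along the stage axis. Maps are reordered
#' by their step index, so voxel slice z always corresponds to stage step
#' z (in the order the steps were acquired).
#'
#' @param maps list of \linkS4class{ActivityMap}.
#' @param pixelSizeUm in-plane pixel size in micrometres.
#' @param stepSizeUm stage step increment in micrometres.
#' @return an \linkS4class{ActivityVolume}.
#' @export
stackMaps <- function(maps, pixelSizeUm, stepSizeUm) {
  stopifnot(length(maps) >= 1)
  steps <- vapply(maps, function(m) m@stepIndex, integer(1))
  maps <- maps[order(steps)]
  d1 <- dim(maps[[1]]@values)
  for (m in maps) {
    if (!identical(dim(m@values), d1))
      stop("activity map for step ", m@stepIndex,
           " has mismatched dimensions")
  }
  arr <- array(0, dim = c(d1[1], d1[2], length(maps)))
  for (z in seq_along(maps)) arr[, , z] <- maps[[z]]@values
  new("ActivityVolume", voxels = arr,
      voxelSizeUm = c(x = pixelSizeUm, y = pixelSizeUm, z = stepSizeUm))
}

#' Crop a volume to a region of interest
#'
#' Crops to an axis-aligned box containing the suspended nematodes.
#' Coordinates are 0-based and half-open on the upper bound:
#' \code{roi = c(x0, y0, z0, x1, y1, z1)} keeps voxels with
#' \code{x0 <= x < x1} etc.
#'
#' @param volume an \linkS4class{ActivityVolume}.
#' @param roi integer vector of length 6.
#' @return the cropped \linkS4class{ActivityVolume}.
#' @export
cropRoi <- function(volume, roi) {
  stopifnot(is(volume, "ActivityVolume"), length(roi) == 6)
  d <- dim(volume@voxels)   # [y, x, z]
  lo <- as.integer(roi[1:3]); hi <- as.integer(roi[4:6])
  if (any(lo < 0) || any(hi > c(d[2], d[1], d[3])) || any(hi <= lo))
    stop("region of interest out of bounds or empty: [",
         paste(roi, collapse = ", "), "] in volume ",
         paste(c(d[2], d[1], d[3]), collapse = " x "))
  out <- volume@voxels[(lo[2] + 1):hi[2], (lo[1] + 1):hi[1],
                       (lo[3] + 1):hi[3], drop = FALSE]
  new("ActivityVolume", voxels = out, voxelSizeUm = volume@voxelSizeUm)
}

#' Subtract the smooth background of each slice
#'
#' Estimates the background of every z slice by grayscale morphological
#' opening with a disc of the given physical radius (the flat equivalent
#' of rolling-ball background subtraction) and subtracts it, clipping at
#' zero. The radius is an in-plane physical length: the structuring
#' element radius in pixels is \code{radius_mm * 1000 / pixelSizeUm}.
#' Background estimation is 2D per slice because the stage spacing is
#' coarse compared to the pixel pitch. A spatially uniform slice maps to
#' zero. Radii larger than the slice diagonal are capped there (beyond it
#' the opening no longer changes).
#'
#' @param volume an \linkS4class{ActivityVolume}.
#' @param radiusMm background radius in millimetres (> 0).
#' @param pixelSizeUm in-plane pixel size; defaults to the volume's.
#' @return the background-subtracted \linkS4class{ActivityVolume}.
#' @export
subtractBackground <- function(volume, radiusMm = 2,
                               pixelSizeUm = voxelSizeUm(volume)[["x"]]) {
  stopifnot(is(volume, "ActivityVolume"))
  if (radiusMm <= 0) stop("background radius must be positive")
  d <- dim(volume@voxels)
  h <- d[1]; w <- d[2]; nz <- d[3]
  r <- max(1L, as.integer(round(radiusMm * 1000 / pixelSizeUm)))
  r <- min(r, as.integer(ceiling(sqrt(h^2 + w^2))))
  # All slices are processed in one matrix, laid out side by side with
  # r neutral separator columns: no chord of the disc (half-width <= r)
  # can reach across a separator, so each slice sees only itself.
  starts <- r + (seq_len(nz) - 1L) * (w + r) + 1L
  sliceCols <- unlist(lapply(starts, function(s) s:(s + w - 1L)))
  M <- matrix(Inf, h, nz * w + (nz + 1L) * r)
  M[, sliceCols] <- volume@voxels
  E <- discFilter(M, r, pmin)
  E[, -sliceCols] <- -Inf
  B <- discFilter(E, r, pmax)
  out <- volume@voxels
  out[] <- pmax(volume@voxels - array(B[, sliceCols], dim = d), 0)
  new("ActivityVolume", voxels = out, voxelSizeUm = volume@voxelSizeUm)
}

#' Per-slice median filter
#'
#' Applies a 2D median over the (2r+1)^2 window to every z slice, with
#' reflected (edge-duplicating) boundary handling.
#'
#' @param volume an \linkS4class{ActivityVolume}.
#' @param radiusPx integer window radius (>= 1).
#' @return the filtered \linkS4class{ActivityVolume}.
#' @export
medianFilterVolume <- function(volume, radiusPx = 1L) {
  stopifnot(is(volume, "ActivityVolume"))
  radiusPx <- as.integer(radiusPx)
  if (radiusPx < 1L) stop("median radius must be >= 1")
  d <- dim(volume@voxels)
  out <- volume@voxels
  offs <- expand.grid(dy = -radiusPx:radiusPx, dx = -radiusPx:radiusPx)
  K <- nrow(offs)
  mid <- (K + 1L) %/% 2L
  ri <- lapply(seq_len(K), function(k)
    reflectIndex(seq_len(d[1]) + offs$dy[k], d[1]))
  ci <- lapply(seq_len(K), function(k)
    reflectIndex(seq_len(d[2]) + offs$dx[k], d[2]))
  for (z in seq_len(d[3])) {
    sl <- volume@voxels[, , z]
    gathered <- vapply(seq_len(K),
                       function(k) as.vector(sl[ri[[k]], ci[[k]]]),
                       numeric(d[1] * d[2]))
    out[, , z] <- matrix(rowSort(gathered)[, mid], d[1], d[2])
  }
  new("ActivityVolume", voxels = out, voxelSizeUm = volume@voxelSizeUm)
}

# 1D Gaussian kernel sampled at integer offsets, normalised to sum 1.
gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Convolve along one axis of a [y, x, z] array with reflected boundaries.
convolveAxis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  n <- d[axis]
  idx <- reflectIndex((1L - r):(n + r), n)
  padded <- switch(axis,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
  out <- array(0, dim = d)
  for (t in seq_along(kernel)) {
    sl <- switch(axis,
                 padded[t:(t + n - 1L), , , drop = FALSE],
                 padded[, t:(t + n - 1L), , drop = FALSE],
                 padded[, , t:(t + n - 1L), drop = FALSE])
    out <- out + kernel[t] * sl
  }
  out
}

#' 3D Gaussian blur
#'
#' Separable 3D Gaussian convolution with per-axis sigmas in voxel units
#' and reflected boundaries. The kernel is the integer-sampled Gaussian
#' normalised to unit sum (support radius \code{ceiling(4 sigma)}), so an
#' interior point source conserves its total intensity. \code{sigma = 0}
#' on an axis leaves that axis untouched.
#'
#' @param volume an \linkS4class{ActivityVolume}.
#' @param sigmaVox numeric length-3 sigma \code{c(sx, sy, sz)} in voxels.
#' @return the blurred \linkS4class{ActivityVolume}.
#' @export
gaussianBlur3d <- function(volume, sigmaVox = c(1, 1, 1)) {
  stopifnot(is(volume, "ActivityVolume"), length(sigmaVox) == 3)
  if (any(sigmaVox < 0)) stop("Gaussian sigma must be >= 0")
  arr <- volume@voxels
  # sigmaVox is (sx, sy, sz); array axes are [y, x, z]
  arr <- convolveAxis(arr, gaussianKernel1d(sigmaVox[2]), 1L)
  arr <- convolveAxis(arr, gaussianKernel1d(sigmaVox[1]), 2L)
  arr <- convolveAxis(arr, gaussianKernel1d(sigmaVox[3]), 3L)
  arr[arr < 0] <- 0
  new("ActivityVolume", voxels = arr, voxelSizeUm = volume@voxelSizeUm)
}

#' Run the full per-scan processing chain
#'
#' Loads every step of a scan, reduces each burst to a generalized
#' differences activity map, stacks the maps into a volume and applies the
#' filtering chain in its fixed order: crop to the region of interest,
#' background subtraction, per-slice median filter, 3D Gaussian blur.
#'
#' @param manifest a \linkS4class{ScanManifest}.
#' @param config a \code{\link{bspimConfig}} list.
#' @return the filtered \linkS4class{ActivityVolume}.
#' @export
processScan <- function(manifest, config = bspimConfig()) {
  stopifnot(is(manifest, "ScanManifest"))
  maps <- lapply(manifest@steps, function(s) {
    st <- loadFrameStack(manifest, s$index)
    bspimLog("speckle_map", "generalized differences",
             sampleId = manifest@sampleId, step = s$index)
    generalizedDifferences(st, config$normalization)
  })
  vol <- stackMaps(maps, manifest@pixelSizeUm, manifest@stepSizeUm)
  bspimLog("volume_pipeline", "pipeline order: crop -> background -> median -> gaussian",
           sampleId = manifest@sampleId)
  if (!is.null(config$roi)) vol <- cropRoi(vol, config$roi)
  vol <- subtractBackground(vol, config$background_radius_mm,
                            manifest@pixelSizeUm)
  vol <- medianFilterVolume(vol, config$median_radius_px)
  gaussianBlur3d(vol, config$gaussian_sigma_vox)
}
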