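# Shape descriptors of detected objects: 2D projections onto the XY plane
# (facing the objective) and the YZ plane (perpendicular to the light
# sheet), convex hulls fitted to the projected pixel centres, hull area S,
# hull perimeter P, circularity 4*pi*S/P^2 and integrated density.
# Motile worms leave drawn-out, low-circularity traces; stationary ones
# compact, near-circular areas.

#' Project a detected object onto a 2D plane
#'
#' Projects the object's voxels along the collapsed axis. The mask is the
#' set of projected pixels hit by at least one object voxel; the per-pixel
#' intensity is the maximum grey value of the object's voxels along the
#' collapsed axis. For the YZ plane the v (z) axis carries a physical
#' rescale factor \code{voxel_z / voxel_y} (anisotropic stage spacing),
#' applied when the hull is fitted.
#'
#' @param object a \linkS4class{DetectedObject}.
#' @param volume the \linkS4class{ActivityVolume} the object was detected
#'   in.
#' @param plane \code{"XY"} or \code{"YZ"}.
#' @param physicalAspect logical; apply the physical z rescale for YZ
#'   (default TRUE).
#' @return a \linkS4class{BiospeckleArea}.
#' @export
projectObject <- function(object, volume, plane = c("XY", "YZ"),
                          physicalAspect = TRUE) {
  stopifnot(is(object, "DetectedObject"), is(volume, "ActivityVolume"))
  plane <- match.arg(plane)
  vox <- object@voxels                     # 0-based x, y, z
  if (nrow(vox) == 0L) stop("cannot project an empty object")
  vals <- volume@voxels[cbind(vox[, "y"] + 1L, vox[, "x"] + 1L,
                              vox[, "z"] + 1L)]
  if (plane == "XY") {
    u <- vox[, "x"]; v <- vox[, "y"]; vScale <- 1
  } else {
    u <- vox[, "y"]; v <- vox[, "z"]
    vs <- volume@voxelSizeUm
    vScale <- if (physicalAspect) vs[["z"]] / vs[["y"]] else 1
  }
  W <- max(u) + 1
  key <- u + W * v
  inten <- tapply(vals, key, max)          # keys sort numerically
  uk <- as.numeric(names(inten))
  px <- cbind(u = as.integer(uk %% W), v = as.integer(uk %/% W))
  new("BiospeckleArea", plane = plane,
      pixels = px, intensities = as.numeric(inten), vScale = vScale)
}

shoelaceArea <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

polyPerimeter <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}

isDegenerate <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3L) return(TRUE)
  a <- pts[1, ]; b <- pts[2, ]
  cross <- (pts[, 1] - a[1]) * (b[2] - a[2]) -
           (pts[, 2] - a[2]) * (b[1] - a[1])
  all(abs(cross) < 1e-9)
}

#' Convex hull of a projected biospeckle area
#'
#' Fits the convex hull to the pixel centres of the projected mask (with
#' the YZ physical rescale applied first) and returns the hull polygon
#' with its area S and perimeter P. Degenerate masks (fewer than three
#' distinct points, or collinear) are padded by a half-pixel square per
#' pixel so that P > 0 and the circularity stays defined for tiny objects.
#'
#' @param area a \linkS4class{BiospeckleArea}.
#' @return a \linkS4class{ShapeDescriptor}.
#' @examples
#' px <- cbind(u = c(0L, 9L, 0L, 9L), v = c(0L, 0L, 9L, 9L))
#' a <- new("BiospeckleArea", plane = "XY", pixels = px,
#'          intensities = rep(1, 4), vScale = 1)
#' s <- convexHullShape(a)
#' hullArea(s); hullPerimeter(s)   # 81 and 36
#' @export
convexHullShape <- function(area) {
  stopifnot(is(area, "BiospeckleArea"))
  pts <- cbind(area@pixels[, "u"], area@pixels[, "v"] * area@vScale)
  if (isDegenerate(pts)) {
    du <- c(-0.5, 0.5, 0.5, -0.5)
    dv <- c(-0.5, -0.5, 0.5, 0.5) * area@vScale
    pts <- cbind(rep(pts[, 1], each = 4) + du,
                 rep(pts[, 2], each = 4) + dv)
  }
  pts <- unique(pts)
  hv <- pts[grDevices::chull(pts), , drop = FALSE]
  S <- shoelaceArea(hv)
  P <- polyPerimeter(hv)
  new("ShapeDescriptor", plane = area@plane, hullVertices = hv,
      hullArea = S, hullPerimeter = P, circularity = circularity(S, P),
      integratedDensity = integratedDensity(area))
}

#' Circularity of a convex hull
#'
#' \deqn{C_A = 4 \pi S / P^2.} A circularity of 1 describes a perfect
#' circle; drawn-out biospeckle traces of motile nematodes give low
#' values. The isoperimetric inequality bounds exact convex polygons at 1.
#'
#' @param S hull area (or a \linkS4class{ShapeDescriptor}).
#' @param P hull perimeter (> 0), ignored when \code{S} is a
#'   \linkS4class{ShapeDescriptor}.
#' @return numeric circularity.
#' @examples
#' circularity(1, 4)         # unit square: pi/4
#' @export
circularity <- function(S, P) {
  if (is(S, "ShapeDescriptor")) return(S@circularity)
  if (P <= 0) stop("hull perimeter must be positive")
  4 * pi * S / P^2
}

#' Minimum circularity over the XY and YZ projections
#'
#' Computes the hull circularity of the object's projection in each plane
#' and returns the minimum with its plane and the full descriptors. The
#' minimum over the two orthogonal projections is the shape readout used
#' to separate stationary from motile nematodes.
#'
#' @param object a \linkS4class{DetectedObject}.
#' @param volume the source \linkS4class{ActivityVolume}.
#' @param planes character vector of planes to consider.
#' @param physicalAspect logical, see \code{\link{projectObject}}.
#' @return list with \code{circularity}, \code{plane} and
#'   \code{descriptors} (named list of \linkS4class{ShapeDescriptor}).
#' @export
minCircularity <- function(object, volume, planes = c("XY", "YZ"),
                           physicalAspect = TRUE) {
  stopifnot(length(planes) >= 1)
  desc <- lapply(planes, function(p)
    convexHullShape(projectObject(object, volume, p, physicalAspect)))
  names(desc) <- planes
  ca <- vapply(desc, function(d) d@circularity, numeric(1))
  k <- which.min(ca)
  list(circularity = unname(ca[k]), plane = planes[k], descriptors = desc)
}

#' Integrated density of a projected area
#'
#' Sum of the projected grey values over the mask pixels.
#'
#' @param area a \linkS4class{BiospeckleArea}.
#' @return numeric scalar.
#' @export
integratedDensity <- function(area) {
  stopifnot(is(area, "BiospeckleArea"))
  sum(area@intensities)
}

#' Per-object shape descriptor table
#'
#' One row per object and projection plane: hull area, perimeter,
#' circularity, integrated density and a flag marking the plane of the
#' minimum circularity.
#'
#' @param result a \linkS4class{SampleResult}.
#' @param volume the source \linkS4class{ActivityVolume}.
#' @param planes planes to include.
#' @param physicalAspect logical, see \code{\link{projectObject}}.
#' @return a data.frame.
#' @export
shapeTable <- function(result, volume, planes = c("XY", "YZ"),
                       physicalAspect = TRUE) {
  stopifnot(is(result, "SampleResult"))
  rows <- list()
  for (o in result@objects) {
    mc <- minCircularity(o, volume, planes, physicalAspect)
    for (p in planes) {
      d <- mc$descriptors[[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = result@sampleId, label = o@label, plane = p,
        hull_area = d@hullArea, hull_perimeter = d@hullPerimeter,
        circularity = d@circularity,
        integrated_density = d@integratedDensity,
        is_min_circularity = identical(p, mc$plane))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sample_id = character(0), label = integer(0),
                      plane = character(0), hull_area = numeric(0),
                      hull_perimeter = numeric(0), circularity = numeric(0),
                      integrated_density = numeric(0),
                      is_min_circularity = logical(0)))
  }
  do.call(rbind, rows)
}
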