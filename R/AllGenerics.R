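# Accessor generics: slot access stays behind these.

#' @rdname accessors
#' @param object a bspim S4 object
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("stepIndex", function(object) standardGeneric("stepIndex"))
#' @rdname accessors
#' @export
setGeneric("activityValues", function(object) standardGeneric("activityValues"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSizeUm", function(object) standardGeneric("voxelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("objectLabel", function(object) standardGeneric("objectLabel"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("meanIntensity", function(object) standardGeneric("meanIntensity"))
#' @rdname accessors
#' @export
setGeneric("centroid", function(object) standardGeneric("centroid"))
#' @rdname accessors
#' @export
setGeneric("boundingBox", function(object) standardGeneric("boundingBox"))
#' @rdname accessors
#' @export
setGeneric("detectedObjects", function(object) standardGeneric("detectedObjects"))
#' @rdname accessors
#' @export
setGeneric("hullArea", function(object) standardGeneric("hullArea"))
#' @rdname accessors
#' @export
setGeneric("hullPerimeter", function(object) standardGeneric("hullPerimeter"))
#' @rdname accessors
#' @export
setGeneric("projectionPlane", function(object) standardGeneric("projectionPlane"))

#' Accessors for bspim classes
#'
#' Small accessor methods exposing the slots of the core data classes.
#'
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
setMethod("sampleId", "ScanManifest", function(object) object@sampleId)
#' @rdname accessors
setMethod("sampleId", "SampleResult", function(object) object@sampleId)
#' @rdname accessors
setMethod("frames", "FrameStack", function(object) object@frames)
#' @rdname accessors
setMethod("stepIndex", "FrameStack", function(object) object@stepIndex)
#' @rdname accessors
setMethod("stepIndex", "ActivityMap", function(object) object@stepIndex)
#' @rdname accessors
setMethod("activityValues", "ActivityMap", function(object) object@values)
#' @rdname accessors
setMethod("voxels", "ActivityVolume", function(object) object@voxels)
#' @rdname accessors
setMethod("voxels", "DetectedObject", function(object) object@voxels)
#' @rdname accessors
setMethod("voxelSizeUm", "ActivityVolume", function(object) object@voxelSizeUm)
#' @rdname accessors
setMethod("objectLabel", "DetectedObject", function(object) object@label)
#' @rdname accessors
setMethod("nVoxels", "DetectedObject", function(object) object@nVoxels)
#' @rdname accessors
setMethod("meanIntensity", "DetectedObject", function(object) object@meanIntensity)
#' @rdname accessors
setMethod("centroid", "DetectedObject", function(object) object@centroid)
#' @rdname accessors
setMethod("boundingBox", "DetectedObject", function(object) object@bbox)
#' @rdname accessors
setMethod("detectedObjects", "SampleResult", function(object) object@objects)
#' @rdname accessors
setMethod("hullArea", "ShapeDescriptor", function(object) object@hullArea)
#' @rdname accessors
setMethod("hullPerimeter", "ShapeDescriptor", function(object) object@hullPerimeter)
#' @rdname accessors
setMethod("projectionPlane", "ShapeDescriptor", function(object) object@plane)
#' @rdname accessors
setMethod("projectionPlane", "BiospeckleArea", function(object) object@plane)
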