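#' Accessors for imaging objects
#'
#' \code{voxels} returns the raw 3D array of a [VolumeGrid-class],
#' \code{maskArray} the integer array of a [LabelMask-class];
#' \code{spacing} and \code{origin} the grid geometry in mm;
#' \code{imageUnit} the value unit tag; \code{voxelVolumeMl} the volume of
#' one voxel in mL.
#'
#' @param x a VolumeGrid or LabelMask.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("imageUnit", function(x) standardGeneric("imageUnit"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' @rdname accessors
#' @export
setMethod("voxels", "VolumeGrid", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("maskArray", "LabelMask", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("spacing", "VolumeGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("spacing", "LabelMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("origin", "VolumeGrid", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("origin", "LabelMask", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("imageUnit", "VolumeGrid", function(x) x@unit)

#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "VolumeGrid", function(x) prod(x@spacing) / 1000)

#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "LabelMask", function(x) prod(x@spacing) / 1000)

#' @rdname accessors
#' @export
setMethod("dim", "VolumeGrid", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

#' AcquisitionMeta accessors
#'
#' @param x an [AcquisitionMeta-class].
#' @name meta-accessors
NULL

#' @rdname meta-accessors
#' @export
setGeneric("injectedActivity", function(x) standardGeneric("injectedActivity"))

#' @rdname meta-accessors
#' @export
setGeneric("bodyMass", function(x) standardGeneric("bodyMass"))

#' @rdname meta-accessors
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname meta-accessors
#' @export
setGeneric("uptakeMinutes", function(x) standardGeneric("uptakeMinutes"))

#' @rdname meta-accessors
#' @export
setGeneric("rescaleSlope", function(x) standardGeneric("rescaleSlope"))

#' @rdname meta-accessors
#' @export
setGeneric("rescaleIntercept", function(x) standardGeneric("rescaleIntercept"))

#' @rdname meta-accessors
#' @export
setGeneric("injectedAtScan", function(x) standardGeneric("injectedAtScan"))

#' @rdname meta-accessors
#' @export
setMethod("injectedActivity", "AcquisitionMeta", function(x) x@injectedActivity)

#' @rdname meta-accessors
#' @export
setMethod("bodyMass", "AcquisitionMeta", function(x) x@bodyMass)

#' @rdname meta-accessors
#' @export
setMethod("halfLife", "AcquisitionMeta", function(x) x@halfLife)

#' @rdname meta-accessors
#' @export
setMethod("uptakeMinutes", "AcquisitionMeta", function(x)
    as.numeric(difftime(x@tScanStart, x@tInjection, units = "mins")))

#' @rdname meta-accessors
#' @export
setMethod("rescaleSlope", "AcquisitionMeta", function(x) x@rescaleSlope)

#' @rdname meta-accessors
#' @export
setMethod("rescaleIntercept", "AcquisitionMeta", function(x) x@rescaleIntercept)

#' @rdname meta-accessors
#' @export
setMethod("injectedAtScan", "AcquisitionMeta", function(x)
    decayCorrectActivity(x@injectedActivity, uptakeMinutes(x), x@halfLife))
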