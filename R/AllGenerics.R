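#' Accessors for image containers
#'
#' `voxelData()` returns the raw 3D (or 4D) array, `spacing()` the
#' voxel spacing in mm, `axesTags()` the axis-orientation labels,
#' `validMask()` the logical validity grid of a parametric map and
#' `mapKind()` its parameter kind.
#'
#' @param x a [VolumeGrid-class], [RelaxometrySeries-class] or
#'   [ParametricMap-class] object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("axesTags", function(x) standardGeneric("axesTags"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @rdname accessors
setMethod("voxelData", "VolumeGrid", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "RelaxometrySeries", function(x) x@signals)
#' @rdname accessors
setMethod("voxelData", "ParametricMap", function(x) x@values@voxels)

#' @rdname accessors
setMethod("spacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "RelaxometrySeries", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "ParametricMap", function(x) x@values@spacing)

#' @rdname accessors
setMethod("axesTags", "VolumeGrid", function(x) x@axes)
#' @rdname accessors
setMethod("axesTags", "RelaxometrySeries", function(x) x@axes)

#' @rdname accessors
setMethod("validMask", "ParametricMap", function(x) x@validMask)
#' @rdname accessors
setMethod("mapKind", "ParametricMap", function(x) x@kind)
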