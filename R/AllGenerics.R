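#' @rdname VoxelGrid-class
#' @param x,object a VoxelGrid or StructureMask.
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname StructureMask-class
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname StructureMask-class
#' @export
setGeneric("rleTransitions", function(x) standardGeneric("rleTransitions"))

#' @rdname StructureMask-class
#' @export
setGeneric("roiName", function(x) standardGeneric("roiName"))

#' Number of set voxels in a mask
#' @param x a [StructureMask-class].
#' @return integer count of set voxels.
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Dense array form of a mask
#' @param x a [StructureMask-class].
#' @return a 3D integer array of 0/1 with dimensions \code{gridDims(x)}.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Voxel index triples of the set voxels
#'
#' Reconstructs the full set of 0-based \code{(x, y, z)} index triples from
#' the run-length encoded mask by expanding every run (not only the
#' transition points) and inverting the x-fastest linearization:
#' \code{z = floor(i / (xDim*yDim))},
#' \code{y = floor((i - z*xDim*yDim) / xDim)},
#' \code{x = i - z*xDim*yDim - y*xDim}.
#'
#' @param x a [StructureMask-class].
#' @return an integer matrix with one row per set voxel and columns
#'   \code{x}, \code{y}, \code{z} (0-based), ordered by linear index.
#' @export
setGeneric("voxelIndices", function(x) standardGeneric("voxelIndices"))

#' Physical volume of a mask
#' @param mask a [StructureMask-class].
#' @return volume in mm^3: set-voxel count times the voxel volume.
#' @export
setGeneric("computeVolume", function(mask) standardGeneric("computeVolume"))

#' Per-axis extent of a mask
#'
#' The extent along an axis is the range of occupied voxel indices,
#' \code{max - min}, reported both in voxels (\code{range_voxels}, plus the
#' inclusive \code{span_voxels = range_voxels + 1}) and in millimetres
#' (\code{range_mm = range_voxels * spacing}).
#'
#' @param mask a non-empty [StructureMask-class].
#' @return a data.frame with rows \code{lr}, \code{ap}, \code{is} and columns
#'   \code{min_index}, \code{max_index}, \code{range_voxels},
#'   \code{span_voxels}, \code{range_mm}.
#' @export
setGeneric("computeExtent", function(mask) standardGeneric("computeExtent"))

#' Slice-based extent profile along the inferior-superior axis
#'
#' Iterates over the occupied z-slices of a contour, recording the left-right
#' and anterior-posterior extents (in mm) of each slice, and summarises the
#' spread of those per-slice extents as their range (max - min) over the
#' occupied slices.
#'
#' @param mask a non-empty [StructureMask-class].
#' @return a list with \code{perSlice} (data.frame: \code{z_index},
#'   \code{lr_range_mm}, \code{ap_range_mm}; occupied slices only),
#'   \code{lr_range_of_ranges_mm} and \code{ap_range_of_ranges_mm}.
#' @export
setGeneric("sliceExtents", function(mask) standardGeneric("sliceExtents"))

#' @rdname ContiguityVerdict-class
#' @param x a ContiguityVerdict.
#' @export
setGeneric("isContiguous", function(x) standardGeneric("isContiguous"))

#' @rdname ContiguityVerdict-class
#' @export
setGeneric("verdictDetail", function(x) standardGeneric("verdictDetail"))
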