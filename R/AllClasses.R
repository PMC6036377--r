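#' @import methods
NULL

#' Regular voxel grid with anisotropic physical spacing
#'
#' A \code{VoxelGrid} records the voxel counts of a regular 3D grid in the
#' left-right (x), anterior-posterior (y) and inferior-superior (z)
#' directions, together with the physical voxel spacing in millimetres along
#' each axis. The grid owns the linearization convention used throughout the
#' package: voxel \code{(x, y, z)} (0-based) has linear index
#' \code{z * xDim * yDim + y * xDim + x}, i.e. x varies fastest.
#'
#' @slot dims integer vector of length 3: voxel counts along x, y, z (all >= 1).
#' @slot spacing numeric vector of length 3: mm per voxel along x, y, z (all > 0).
#'
#' @seealso [VoxelGrid()], [StructureMask]
#' @export
setClass("VoxelGrid", representation(dims = "integer", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (length(object@dims) != 3L || anyNA(object@dims))
    return("dims must be an integer vector of length 3")
  if (any(object@dims < 1L))
    return("all grid dimensions must be >= 1")
  if (length(object@spacing) != 3L || anyNA(object@spacing))
    return("spacing must be a numeric vector of length 3")
  if (any(object@spacing <= 0))
    return("all voxel spacings must be > 0 mm")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param dims integer vector of length 3: voxel counts along x (left-right),
#'   y (anterior-posterior) and z (inferior-superior).
#' @param spacing numeric vector of length 3: voxel spacing in mm along the
#'   same axes. Defaults to isotropic 1 mm.
#' @return A [VoxelGrid-class] object.
#' @examples
#' VoxelGrid(c(64, 64, 80), c(1, 1, 2))
#' @export
VoxelGrid <- function(dims, spacing = c(1, 1, 1)) {
  new("VoxelGrid", dims = as.integer(dims), spacing = as.numeric(spacing))
}

#' Binary structure mask bound to a voxel grid
#'
#' A \code{StructureMask} holds one region of interest's binary mask in
#' run-length encoded form: the strictly increasing 0-based linear indices at
#' which the linearized mask switches between 0 and 1, interpreted as
#' half-open runs \code{[t1, t2), [t3, t4), ...}. The encoding is lossless;
#' the dense array form is available through [maskArray()].
#'
#' @slot grid the [VoxelGrid-class] the mask lives on.
#' @slot transitions strictly increasing 0-based linear indices, even count,
#'   all within \code{0 .. prod(dims)}.
#' @slot roiName label of the region of interest (may be empty).
#'
#' @seealso [StructureMask()], [maskArray()], [voxelIndices()], [voxelCount()]
#' @export
setClass("StructureMask",
         representation(grid = "VoxelGrid", transitions = "integer",
                        roiName = "character"))

setValidity("StructureMask", function(object) {
  tr <- object@transitions
  if (anyNA(tr)) return("transitions must not contain NA")
  if (length(tr) %% 2L != 0L)
    return("transition count must be even (half-open run pairs)")
  if (length(tr) > 1L && any(diff(tr) <= 0L))
    return("transitions must be strictly increasing")
  total <- prod(as.numeric(object@grid@dims))
  if (length(tr) && (tr[1L] < 0L || tr[length(tr)] > total))
    return(sprintf("transitions must lie in [0, %d]", as.integer(total)))
  if (length(object@roiName) != 1L)
    return("roiName must be a single string")
  TRUE
})

#' Construct a StructureMask
#'
#' Accepts either a dense 3D binary array (dimensions must match the grid) or
#' an already run-length encoded transition vector.
#'
#' @param x a 3D array of 0/1 (or logical) values, or a numeric vector of
#'   strictly increasing 0-based transition indices (even count).
#' @param grid a [VoxelGrid-class]. When \code{x} is an array and \code{grid}
#'   is missing, a unit-spacing grid matching \code{dim(x)} is used.
#' @param roiName optional region-of-interest label.
#' @return A [StructureMask-class].
#' @examples
#' g <- VoxelGrid(c(1, 1, 8))
#' m <- StructureMask(c(2, 5), g)   # voxels at linear indices 2, 3, 4
#' voxelCount(m)
#' @export
StructureMask <- function(x, grid, roiName = "") {
  if (is.array(x)) {
    if (missing(grid)) grid <- VoxelGrid(dim(x))
    tr <- rleEncode(x, grid)
  } else {
    if (missing(grid))
      .validationError("a grid is required when constructing from transitions")
    tr <- as.integer(x)
    if (length(tr) %% 2L != 0L)
      .validationError("transition count must be even, got %d", length(tr))
    if (length(tr) > 1L && any(diff(tr) <= 0L))
      .validationError("transitions must be strictly increasing")
    if (length(tr) && (tr[1L] < 0L || tr[length(tr)] > prod(grid@dims)))
      .validationError("transitions exceed the grid (total %d voxels)",
                       prod(grid@dims))
  }
  new("StructureMask", grid = grid, transitions = tr,
      roiName = as.character(roiName))
}

#' Outcome of a contiguity check
#'
#' @slot method one of \code{"extent"}, \code{"region_growing"},
#'   \code{"oracle"}.
#' @slot contiguous \code{TRUE}, \code{FALSE}, or \code{NA} for an empty mask
#'   (an empty clinical contour is neither contiguous nor noncontiguous; the
#'   cohort layer flags it separately).
#' @slot detail method-specific diagnostics: per-axis gap positions for the
#'   extent check; visited/total counts for region growing; component count
#'   and sizes for the brute-force oracle.
#' @seealso [checkExtentContiguity()], [checkRegionGrowingContiguity()],
#'   [connectedComponentsOracle()], [isContiguous()]
#' @export
setClass("ContiguityVerdict",
         representation(method = "character", contiguous = "logical",
                        detail = "list"))

setValidity("ContiguityVerdict", function(object) {
  if (!object@method %in% c("extent", "region_growing", "oracle"))
    return("method must be one of extent, region_growing, oracle")
  if (length(object@contiguous) != 1L)
    return("contiguous must be a single logical (NA allowed for empty masks)")
  TRUE
})
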