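# ---- RLE codec and index arithmetic ------------------------------------
# Linearization is x-fastest: linear = z*X*Y + y*X + x (0-based), which is
# R's native column-major order for an array of dim c(X, Y, Z).

#' Run-length encode a dense binary mask
#'
#' Scans the x-fastest linearization of the array and records every 0->1 and
#' 1->0 boundary as a 0-based transition index; runs are half-open
#' \code{[t1, t2)}, and a run touching the final voxel closes at
#' \code{prod(dims)}.
#'
#' @param dense a 3D array of 0/1, logical or numeric.
#' @param grid a [VoxelGrid-class] whose dims must match \code{dim(dense)}.
#' @return integer vector of transitions (even length, strictly increasing).
#' @examples
#' g <- VoxelGrid(c(1, 1, 8))
#' a <- array(0L, c(1, 1, 8)); a[1, 1, 3:5] <- 1L
#' rleEncode(a, g)   # c(2, 5)
#' @export
rleEncode <- function(dense, grid) {
  if (!is.array(dense) || length(dim(dense)) != 3L)
    .validationError("dense mask must be a 3D array")
  if (!identical(as.integer(dim(dense)), grid@dims))
    .validationError("array dimensions (%s) do not match grid dims (%s)",
                     paste(dim(dense), collapse = "x"),
                     paste(grid@dims, collapse = "x"))
  v <- as.integer(as.vector(dense) != 0)
  d <- diff(c(0L, v, 0L))
  starts <- which(d == 1L) - 1L   # 0-based
  ends   <- which(d == -1L) - 1L  # exclusive
  tr <- integer(2L * length(starts))
  if (length(starts)) {
    tr[seq(1L, length(tr), by = 2L)] <- starts
    tr[seq(2L, length(tr), by = 2L)] <- ends
  }
  tr
}

#' Decode run-length transitions to a dense binary mask
#'
#' @param transitions integer vector of 0-based transitions (even count,
#'   strictly increasing), or a [StructureMask-class].
#' @param grid a [VoxelGrid-class] (ignored when a mask is supplied).
#' @return a 3D integer array of 0/1 with the grid's dimensions; every voxel
#'   strictly inside a run pair is set (interior filling).
#' @export
rleDecode <- function(transitions, grid) {
  if (is(transitions, "StructureMask")) {
    grid <- transitions@grid
    transitions <- transitions@transitions
  }
  tr <- as.integer(transitions)
  if (length(tr) %% 2L != 0L)
    .validationError("transition count must be even, got %d", length(tr))
  if (length(tr) > 1L && any(diff(tr) <= 0L))
    .validationError("transitions must be strictly increasing")
  total <- prod(grid@dims)
  if (length(tr) && (tr[1L] < 0L || tr[length(tr)] > total))
    .validationError("transitions exceed the grid (total %d voxels)", total)
  v <- integer(total)
  if (length(tr)) {
    starts <- tr[seq(1L, length(tr), by = 2L)]
    lens <- tr[seq(2L, length(tr), by = 2L)] - starts
    v[sequence(lens, from = starts + 1L, by = 1L)] <- 1L
  }
  array(v, dim = grid@dims)
}

# 0-based linear indices of all set voxels, expanded from the runs
.setLinearIndices <- function(mask) {
  tr <- mask@transitions
  if (!length(tr)) return(integer(0))
  starts <- tr[seq(1L, length(tr), by = 2L)]
  lens <- tr[seq(2L, length(tr), by = 2L)] - starts
  sequence(lens, from = starts, by = 1L)
}

#' Convert 0-based linear indices to (x, y, z) voxel triples
#'
#' Inverts the x-fastest linearization: \code{z = floor(i / (X*Y))},
#' \code{y = floor((i - z*X*Y) / X)}, \code{x = i - z*X*Y - y*X}.
#'
#' @param i vector of 0-based linear indices.
#' @param grid a [VoxelGrid-class].
#' @return integer matrix with columns \code{x}, \code{y}, \code{z} (0-based).
#' @examples
#' linearToVoxel(13, VoxelGrid(c(4, 3, 2)))  # (1, 0, 1)
#' @export
linearToVoxel <- function(i, grid) {
  i <- as.integer(i)
  X <- grid@dims[1L]; XY <- X * grid@dims[2L]
  z <- i %/% XY
  y <- (i - z * XY) %/% X
  x <- i - z * XY - y * X
  cbind(x = x, y = y, z = z)
}

#' Convert (x, y, z) voxel triples to 0-based linear indices
#' @param xyz integer matrix with columns x, y, z (0-based).
#' @param grid a [VoxelGrid-class].
#' @return integer vector of 0-based linear indices.
#' @export
voxelToLinear <- function(xyz, grid) {
  xyz <- matrix(as.integer(xyz), ncol = 3L)
  X <- grid@dims[1L]; XY <- X * grid@dims[2L]
  xyz[, 3L] * XY + xyz[, 2L] * X + xyz[, 1L]
}

# ---- accessors ----------------------------------------------------------

#' @rdname VoxelGrid-class
setMethod("gridDims", "VoxelGrid", function(x) x@dims)
#' @rdname VoxelGrid-class
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname StructureMask-class
#' @param x a StructureMask.
setMethod("gridDims", "StructureMask", function(x) x@grid@dims)
#' @rdname StructureMask-class
setMethod("gridSpacing", "StructureMask", function(x) x@grid@spacing)
#' @rdname StructureMask-class
setMethod("maskGrid", "StructureMask", function(x) x@grid)
#' @rdname StructureMask-class
setMethod("rleTransitions", "StructureMask", function(x) x@transitions)
#' @rdname StructureMask-class
setMethod("roiName", "StructureMask", function(x) x@roiName)

#' @rdname voxelCount
setMethod("voxelCount", "StructureMask", function(x) {
  tr <- x@transitions
  if (!length(tr)) return(0L)
  as.integer(sum(tr[seq(2L, length(tr), by = 2L)] -
                 tr[seq(1L, length(tr), by = 2L)]))
})

#' @rdname maskArray
setMethod("maskArray", "StructureMask", function(x) rleDecode(x@transitions, x@grid))

#' @rdname voxelIndices
setMethod("voxelIndices", "StructureMask", function(x) {
  linearToVoxel(.setLinearIndices(x), x@grid)
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s voxels, spacing %s mm\n",
              paste(object@dims, collapse = " x "),
              paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "StructureMask", function(object) {
  cat(sprintf("StructureMask%s: %d voxels on %s grid (spacing %s mm), %d RLE runs\n",
              if (nzchar(object@roiName)) paste0(" '", object@roiName, "'") else "",
              voxelCount(object),
              paste(object@grid@dims, collapse = "x"),
              paste(format(object@grid@spacing), collapse = "x"),
              length(object@transitions) %/% 2L))
})

setMethod("show", "ContiguityVerdict", function(object) {
  state <- if (is.na(object@contiguous)) "empty mask"
           else if (object@contiguous) "contiguous" else "NONCONTIGUOUS"
  cat(sprintf("ContiguityVerdict [%s]: %s\n", object@method, state))
})

#' @rdname ContiguityVerdict-class
setMethod("isContiguous", "ContiguityVerdict", function(x) x@contiguous)
#' @rdname ContiguityVerdict-class
setMethod("verdictDetail", "ContiguityVerdict", function(x) x@detail)

# ---- geometric metrics --------------------------------------------------

#' @rdname computeVolume
setMethod("computeVolume", "StructureMask", function(mask) {
  voxelCount(mask) * prod(mask@grid@spacing)
})

#' @rdname computeExtent
setMethod("computeExtent", "StructureMask", function(mask) {
  if (voxelCount(mask) == 0L) .emptyMaskError("computeExtent")
  xyz <- voxelIndices(mask)
  mins <- apply(xyz, 2L, min)
  maxs <- apply(xyz, 2L, max)
  rng <- maxs - mins
  data.frame(
    row.names = c("lr", "ap", "is"),
    min_index = as.integer(mins),
    max_index = as.integer(maxs),
    range_voxels = as.integer(rng),
    span_voxels = as.integer(rng + 1L),
    range_mm = rng * mask@grid@spacing)
})

#' Extent ratios of a mask
#'
#' Dimensionless shape descriptors formed by dividing the physical (mm)
#' extents: lateral / anterior-posterior, lateral / inferior-superior, and
#' anterior-posterior / inferior-superior. When any denominator extent is
#' zero (e.g. a single-voxel or single-slice mask) the ratios are undefined
#' and returned as NA so that cohort models can treat the row as an
#' automatic outlier rather than raising an error.
#'
#' @param extent a per-axis extent data.frame from [computeExtent()], or a
#'   [StructureMask-class] (the extent is computed first).
#' @return named numeric vector \code{lr_over_ap}, \code{lr_over_is},
#'   \code{ap_over_is}; all NA when undefined.
#' @export
extentRatios <- function(extent) {
  if (is(extent, "StructureMask")) extent <- computeExtent(extent)
  r <- extent[c("lr", "ap", "is"), "range_mm"]
  if (any(r == 0))
    return(c(lr_over_ap = NA_real_, lr_over_is = NA_real_, ap_over_is = NA_real_))
  c(lr_over_ap = r[1L] / r[2L], lr_over_is = r[1L] / r[3L],
    ap_over_is = r[2L] / r[3L])
}

#' @rdname sliceExtents
setMethod("sliceExtents", "StructureMask", function(mask) {
  if (voxelCount(mask) == 0L) .emptyMaskError("sliceExtents")
  xyz <- voxelIndices(mask)
  sp <- mask@grid@spacing
  zs <- xyz[, "z"]
  xr <- vapply(split(xyz[, "x"], zs), function(v) diff(range(v)), numeric(1))
  yr <- vapply(split(xyz[, "y"], zs), function(v) diff(range(v)), numeric(1))
  perSlice <- data.frame(z_index = as.integer(names(xr)),
                         lr_range_mm = unname(xr) * sp[1L],
                         ap_range_mm = unname(yr) * sp[2L])
  perSlice <- perSlice[order(perSlice$z_index), , drop = FALSE]
  rownames(perSlice) <- NULL
  list(perSlice = perSlice,
       lr_range_of_ranges_mm = diff(range(perSlice$lr_range_mm)),
       ap_range_of_ranges_mm = diff(range(perSlice$ap_range_mm)))
})
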