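# ---- contiguity checks --------------------------------------------------
# Two routes: (1) axis-projection extent completeness, which only sees whole
# missing coordinate planes, and (2) flood-fill region growing with a fixed
# Euclidean neighbour radius (default sqrt(3), i.e. 26-connectivity on a
# unit-voxel index grid). Radius semantics: [1, sqrt(2)) -> 6-connectivity,
# [sqrt(2), sqrt(3)) -> 18, [sqrt(3), 2) -> 26.

.RADIUS_TOL <- 1e-9

#' Contiguity check configuration
#'
#' @param neighborRadius neighbour search radius in voxel-index units
#'   (voxels are treated as points on a unit grid regardless of physical
#'   spacing). The default \code{sqrt(3)} makes the region-growing closure
#'   exactly 26-connectivity.
#' @param seedRule seed selection rule; only \code{"lowest_linear_index"} is
#'   defined (the verdict is seed-invariant in any case).
#' @return a list of class \code{contiguityConfig}.
#' @export
contiguityConfig <- function(neighborRadius = sqrt(3),
                             seedRule = "lowest_linear_index") {
  if (!is.numeric(neighborRadius) || length(neighborRadius) != 1L ||
      neighborRadius <= 0)
    .validationError("neighborRadius must be a single positive number")
  seedRule <- match.arg(seedRule, "lowest_linear_index")
  structure(list(neighborRadius = neighborRadius, seedRule = seedRule),
            class = "contiguityConfig")
}

# integer displacement vectors with 0 < |d| <= radius (plus tolerance)
.neighborOffsets <- function(radius) {
  rmax <- floor(radius + .RADIUS_TOL)
  if (rmax < 1) return(matrix(integer(0), 0L, 3L))
  s <- seq.int(-rmax, rmax)
  offs <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  d2 <- rowSums(offs^2)
  offs[d2 > 0 & d2 <= radius^2 + .RADIUS_TOL, , drop = FALSE]
}

#' Contiguity by axis-projection extent completeness
#'
#' Projects the occupied voxel coordinates onto each axis and asks whether
#' every integer coordinate between the per-axis minimum and maximum is
#' occupied, i.e. whether the number of unique occupied coordinates equals
#' the inclusive span (range + 1). A whole missing slice or a body projected
#' away from the main contour along an axis leaves a gap; a defect that
#' keeps every axis projection complete is invisible to this check (each
#' projection may be contiguous even when the structure is not).
#'
#' @param mask a [StructureMask-class].
#' @return a [ContiguityVerdict-class] with per-axis
#'   \code{unique_coordinate_count}, \code{span_voxels} and
#'   \code{gap_positions} in its detail; \code{contiguous} is NA for an
#'   empty mask.
#' @export
checkExtentContiguity <- function(mask) {
  if (voxelCount(mask) == 0L)
    return(new("ContiguityVerdict", method = "extent", contiguous = NA,
               detail = list(empty = TRUE)))
  xyz <- voxelIndices(mask)
  axes <- c(lr = 1L, ap = 2L, is = 3L)
  detail <- lapply(axes, function(a) {
    u <- sort(unique(xyz[, a]))
    full <- seq.int(u[1L], u[length(u)])
    list(unique_coordinate_count = length(u),
         span_voxels = length(full),
         gap_positions = setdiff(full, u))
  })
  contiguous <- all(vapply(detail, function(d)
    d$unique_coordinate_count == d$span_voxels, logical(1)))
  new("ContiguityVerdict", method = "extent", contiguous = contiguous,
      detail = detail)
}

#' Flood-fill region growing over a mask
#'
#' Starting from the seed voxel (the set voxel with the lowest linear
#' index), repeatedly adds every unvisited set voxel lying within Euclidean
#' distance \code{neighborRadius} (voxel-index units) of any visited voxel,
#' until a fixed point. The frontier is an explicit queue, never call-stack
#' recursion, so masks of arbitrary size are safe. With the default radius
#' \code{sqrt(3)} the visited set is exactly the 26-connected component of
#' the seed.
#'
#' @param mask a non-empty [StructureMask-class].
#' @param config a [contiguityConfig()].
#' @param seedLinear optional 0-based linear index of a set voxel to seed
#'   from (used by the seed-invariance tests); default is the seed rule.
#' @return sorted integer vector of visited 0-based linear indices.
#' @export
regionGrow <- function(mask, config = contiguityConfig(), seedLinear = NULL) {
  if (voxelCount(mask) == 0L) .emptyMaskError("regionGrow")
  dims <- mask@grid@dims
  X <- dims[1L]; XY <- X * dims[2L]
  set <- as.logical(rleDecode(mask@transitions, mask@grid))
  if (is.null(seedLinear)) {
    seedLinear <- mask@transitions[1L]
  } else {
    seedLinear <- as.integer(seedLinear)
    if (!set[seedLinear + 1L])
      .validationError("seed linear index %d is not a set voxel", seedLinear)
  }
  offs <- .neighborOffsets(config$neighborRadius)
  visited <- logical(length(set))
  visited[seedLinear + 1L] <- TRUE
  frontier <- linearToVoxel(seedLinear, mask@grid)  # 0-based coords
  nOff <- nrow(offs)
  while (nrow(frontier) > 0L && nOff > 0L) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nOff), , drop = FALSE] +
      offs[rep(seq_len(nOff), times = nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1L] >= 0L & nb[, 1L] < dims[1L] &
          nb[, 2L] >= 0L & nb[, 2L] < dims[2L] &
          nb[, 3L] >= 0L & nb[, 3L] < dims[3L]
    lin <- unique(nb[ok, 3L] * XY + nb[ok, 2L] * X + nb[ok, 1L])
    lin <- lin[set[lin + 1L] & !visited[lin + 1L]]
    visited[lin + 1L] <- TRUE
    frontier <- linearToVoxel(lin, mask@grid)
  }
  sort(which(visited) - 1L)
}

#' Contiguity by region growing over volume
#'
#' The mask is contiguous iff the flood fill from the seed visits every set
#' voxel (visited count equals the voxel count).
#'
#' @inheritParams regionGrow
#' @return a [ContiguityVerdict-class] with \code{visited_count} and
#'   \code{total_count} in its detail; \code{contiguous} is NA for an empty
#'   mask.
#' @export
checkRegionGrowingContiguity <- function(mask, config = contiguityConfig()) {
  n <- voxelCount(mask)
  if (n == 0L)
    return(new("ContiguityVerdict", method = "region_growing",
               contiguous = NA, detail = list(empty = TRUE)))
  visited <- regionGrow(mask, config)
  new("ContiguityVerdict", method = "region_growing",
      contiguous = length(visited) == n,
      detail = list(visited_count = length(visited), total_count = n))
}

#' Brute-force connected-components oracle
#'
#' Labels the connected components of the set voxels by exhaustive pairwise
#' Euclidean distance comparison at the configured radius, with no spatial
#' index or neighbour-offset shortcut. Quadratic in the voxel count; meant
#' as an independent verification oracle on small masks, not for production
#' use.
#'
#' @inheritParams regionGrow
#' @return a [ContiguityVerdict-class] whose detail carries
#'   \code{component_count}, \code{component_sizes}, and \code{labels}
#'   (component id per set voxel, in linear-index order).
#' @export
connectedComponentsOracle <- function(mask, config = contiguityConfig()) {
  n <- voxelCount(mask)
  if (n == 0L)
    return(new("ContiguityVerdict", method = "oracle", contiguous = NA,
               detail = list(empty = TRUE)))
  xyz <- voxelIndices(mask)
  r2 <- config$neighborRadius^2 + .RADIUS_TOL
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  adj <- d2 <= r2
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    frontier <- s
    labels[s] <- comp
    while (length(frontier)) {
      reach <- which(labels == 0L &
                     rowSums(adj[, frontier, drop = FALSE]) > 0)
      labels[reach] <- comp
      frontier <- reach
    }
  }
  sizes <- as.integer(tabulate(labels, comp))
  new("ContiguityVerdict", method = "oracle", contiguous = comp == 1L,
      detail = list(component_count = comp, component_sizes = sizes,
                    labels = labels))
}
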