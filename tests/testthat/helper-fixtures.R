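# fixtures are built in code; no binary files

# mask from a list/matrix of 0-based (x, y, z) voxel triples
maskFromVoxels <- function(voxels, dims, spacing = c(1, 1, 1)) {
  if (is.list(voxels)) voxels <- do.call(rbind, voxels)
  a <- array(0L, dim = dims)
  a[voxels + 1L] <- 1L
  StructureMask(a, VoxelGrid(dims, spacing))
}

randomGrid <- function(maxDim = 12L, minDim = 3L) {
  dims <- sample(minDim:maxDim, 3L, replace = TRUE)
  VoxelGrid(dims, stats::runif(3, 0.5, 3))
}

randomMask <- function(grid = randomGrid(), density = stats::runif(1, 0.05, 0.6)) {
  d <- gridDims(grid)
  a <- array(as.integer(stats::runif(prod(d)) < density), dim = d)
  StructureMask(a, grid)
}

# the fixed 4-voxel set whose axis projections are all complete although the
# structure splits into two 26-components
projectionBlindSet <- function() {
  maskFromVoxels(list(c(0, 0, 0), c(1, 1, 1), c(2, 3, 2), c(3, 2, 3)),
                 dims = c(4, 4, 4))
}

# independent second oracle: union-find over the neighbour graph defined by
# exhaustive pairwise Euclidean distance at the given radius
unionFindComponents <- function(mask, radius = sqrt(3)) {
  xyz <- voxelIndices(mask)
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  r2 <- radius^2 + 1e-9
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sum((xyz[i, ] - xyz[j, ])^2) <= r2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  list(count = length(unique(roots)), sizes = sort(tabulate(comp)))
}

# a small solid organ-like phantom on a coarse grid (oracle-friendly size)
smallSpherePhantom <- function(radiusVox = 3, dims = c(9, 9, 9)) {
  ctr <- (dims - 1) / 2
  co <- expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                    z = 0:(dims[3] - 1))
  keep <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2 <=
    radiusVox^2
  maskFromVoxels(as.matrix(co[keep, ]), dims)
}
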