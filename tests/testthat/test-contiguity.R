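test_that("extent contiguity requires complete coordinate ranges per axis", {
  cube <- StructureMask(array(1L, c(3, 3, 3)), VoxelGrid(c(3, 3, 3)))
  expect_true(isContiguous(checkExtentContiguity(cube)))

  a <- array(1L, c(3, 3, 3)); a[, , 2] <- 0L
  gap <- StructureMask(a, VoxelGrid(c(3, 3, 3)))
  v <- checkExtentContiguity(gap)
  expect_false(isContiguous(v))
  expect_equal(verdictDetail(v)$is$gap_positions, 1L)
  expect_equal(verdictDetail(v)$lr$gap_positions, integer(0))

  # all three axis projections complete although the set is disconnected
  expect_true(isContiguous(checkExtentContiguity(projectionBlindSet())))
})

test_that("region growing is the neighbour-radius closure of the seed", {
  single <- maskFromVoxels(list(c(1, 1, 1)), c(3, 3, 3))
  expect_equal(length(regionGrow(single)), 1L)

  diag <- maskFromVoxels(list(c(0, 0, 0), c(1, 1, 1)), c(3, 3, 3))
  expect_equal(length(regionGrow(diag)), 2L)   # distance sqrt(3) <= sqrt(3)

  far <- maskFromVoxels(list(c(0, 0, 0), c(2, 0, 0)), c(3, 3, 3))
  expect_equal(regionGrow(far), 0L)            # distance 2 > sqrt(3)

  expect_error(regionGrow(StructureMask(integer(0), VoxelGrid(c(2, 2, 2)))),
               class = "contourQA_empty_mask_error")
})

test_that("region-growing verdict counts visited against total voxels", {
  sphere <- smallSpherePhantom()
  expect_true(isContiguous(checkRegionGrowingContiguity(sphere)))

  a <- maskArray(sphere)
  a[1, 1, 1] <- 1L  # detached corner voxel, far from the sphere surface
  broken <- StructureMask(a, maskGrid(sphere))
  v <- checkRegionGrowingContiguity(broken)
  expect_false(isContiguous(v))
  expect_equal(verdictDetail(v)$total_count, voxelCount(sphere) + 1L)
  # seeded inside the sphere, the fill visits all but the detached voxel
  sphereSeed <- rleTransitions(sphere)[1]
  expect_equal(length(regionGrow(broken, seedLinear = sphereSeed)),
               voxelCount(sphere))

  vb <- checkRegionGrowingContiguity(projectionBlindSet())
  expect_false(isContiguous(vb))
  oc <- connectedComponentsOracle(projectionBlindSet())
  expect_equal(verdictDetail(oc)$component_count, 2L)
  expect_equal(verdictDetail(oc)$component_sizes, c(2L, 2L))
})

test_that("empty masks get a distinct verdict, neither pass nor fail", {
  empty <- StructureMask(integer(0), VoxelGrid(c(4, 4, 4)))
  expect_true(is.na(isContiguous(checkExtentContiguity(empty))))
  expect_true(is.na(isContiguous(checkRegionGrowingContiguity(empty))))
  expect_true(is.na(isContiguous(connectedComponentsOracle(empty))))
})

test_that("oracle labeling is a brute-force component count", {
  cube <- StructureMask(array(1L, c(3, 3, 3)), VoxelGrid(c(3, 3, 3)))
  expect_equal(verdictDetail(connectedComponentsOracle(cube))$component_count, 1L)

  a <- array(0L, c(3, 3, 8)); a[, , 1:2] <- 1L; a[, , 5:6] <- 1L
  two <- StructureMask(a, VoxelGrid(c(3, 3, 8)))
  expect_equal(verdictDetail(connectedComponentsOracle(two))$component_count, 2L)

  # agreement with an independent union-find over the same neighbour graph
  set.seed(606)
  for (i in 1:100) {
    m <- randomMask()
    if (voxelCount(m) == 0L || voxelCount(m) > 400L) next
    od <- verdictDetail(connectedComponentsOracle(m))
    uf <- unionFindComponents(m)
    expect_equal(od$component_count, uf$count)
    expect_equal(sort(od$component_sizes), uf$sizes)
  }
})

test_that("region growing agrees with the oracle on random masks", {
  set.seed(707)
  for (i in 1:150) {
    m <- randomMask()
    if (voxelCount(m) == 0L) next
    expect_identical(isContiguous(checkRegionGrowingContiguity(m)),
                     verdictDetail(connectedComponentsOracle(m))$component_count == 1L)
  }
})

test_that("the verdict does not depend on the seed voxel", {
  set.seed(808)
  for (i in 1:50) {
    m <- randomMask(VoxelGrid(sample(3:6, 3, replace = TRUE)),
                    density = stats::runif(1, 0.1, 0.5))
    n <- voxelCount(m)
    if (n == 0L || n > 40L) next
    lins <- which(as.vector(maskArray(m)) == 1L) - 1L
    verdicts <- vapply(lins, function(s)
      length(regionGrow(m, seedLinear = s)) == n, logical(1))
    expect_true(all(verdicts) || !any(verdicts))
    expect_equal(verdicts[1],
                 isContiguous(checkRegionGrowingContiguity(m)))
  }
})

test_that("extent-detected breaks are a subset of region-growing breaks", {
  set.seed(909)
  for (i in 1:150) {
    m <- randomMask()
    if (voxelCount(m) == 0L) next
    if (!isContiguous(checkExtentContiguity(m)))
      expect_false(isContiguous(checkRegionGrowingContiguity(m)))
  }
  # the converse fails: projections can be complete on a split structure
  expect_true(isContiguous(checkExtentContiguity(projectionBlindSet())))
  expect_false(isContiguous(checkRegionGrowingContiguity(projectionBlindSet())))
})

test_that("neighbour radius bands give 6/18/26-connectivity", {
  facePair <- maskFromVoxels(list(c(1, 1, 1), c(2, 1, 1)), c(4, 4, 4))
  edgePair <- maskFromVoxels(list(c(1, 1, 1), c(2, 2, 1)), c(4, 4, 4))
  cornerPair <- maskFromVoxels(list(c(1, 1, 1), c(2, 2, 2)), c(4, 4, 4))
  connected <- function(m, r)
    isContiguous(checkRegionGrowingContiguity(m, contiguityConfig(r)))
  for (r in c(1, 1.2)) {             # [1, sqrt(2)): 6-connectivity
    expect_true(connected(facePair, r))
    expect_false(connected(edgePair, r))
    expect_false(connected(cornerPair, r))
  }
  for (r in c(sqrt(2), 1.6)) {       # [sqrt(2), sqrt(3)): 18-connectivity
    expect_true(connected(facePair, r))
    expect_true(connected(edgePair, r))
    expect_false(connected(cornerPair, r))
  }
  for (r in c(sqrt(3), 1.9)) {       # [sqrt(3), 2): 26-connectivity
    expect_true(connected(facePair, r))
    expect_true(connected(edgePair, r))
    expect_true(connected(cornerPair, r))
  }
})

test_that("overlapping drifting disks stay contiguous across slices", {
  # anatomical smoothness: the fill travels between slices through the
  # overlapping interior voxels even as the centroid drifts
  dims <- c(24, 24, 10)
  vox <- list()
  for (z in 0:9) {
    cx <- 6 + z; cy <- 6 + z   # 1 voxel drift per slice
    for (x in 0:23) for (y in 0:23)
      if ((x - cx)^2 + (y - cy)^2 <= 9) vox[[length(vox) + 1L]] <- c(x, y, z)
  }
  stack <- maskFromVoxels(vox, dims)
  expect_true(isContiguous(checkRegionGrowingContiguity(stack)))
})
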