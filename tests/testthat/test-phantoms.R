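test_that("phantom generation is deterministic and organ-shaped", {
  for (organ in c("bladder_full", "bladder_empty", "femoral_ball",
                  "femoral_ball_shaft", "spinal_cord", "rectum",
                  "prostate", "brainstem_like")) {
    m1 <- generatePhantom(phantomSpec(organ, seed = 13))
    m2 <- generatePhantom(phantomSpec(organ, seed = 13))
    expect_identical(rleTransitions(m1), rleTransitions(m2))
    expect_gt(voxelCount(m1), 0L)
    expect_true(isContiguous(checkRegionGrowingContiguity(m1)))
    expect_true(isContiguous(checkExtentContiguity(m1)))
    ext <- computeExtent(m1)
    expect_true(all(ext$min_index >= 1L))
    expect_true(all(ext$max_index <= gridDims(m1) - 2L))
  }
})

test_that("clean phantom connectivity agrees with the brute-force oracle", {
  # oracle-sized renditions of the phantom shapes
  small <- list(
    generatePhantom(phantomSpec("bladder_full",
                                grid = VoxelGrid(c(12, 12, 12), c(4, 4, 4)),
                                semiAxesMm = c(16, 16, 16))),
    generatePhantom(phantomSpec("spinal_cord",
                                grid = VoxelGrid(c(10, 10, 20), c(4, 4, 8)),
                                radiusMm = 6, driftAmpMm = c(2, 2),
                                zMarginSlices = 2, seed = 3)))
  for (m in small) {
    expect_lt(voxelCount(m), 600L)
    expect_equal(verdictDetail(connectedComponentsOracle(m))$component_count, 1L)
  }
})

test_that("a shaft multiplies the inferior-superior extent of a ball", {
  r <- 16
  ball <- generatePhantom(phantomSpec("femoral_ball",
                                      semiAxesMm = c(r, r, r)))
  comp <- generatePhantom(phantomSpec("femoral_ball_shaft",
                                      ballRadiusMm = r,
                                      shaftLengthMm = 6 * r))
  expect_gte(computeExtent(comp)["is", "range_mm"],
             3 * computeExtent(ball)["is", "range_mm"])
})

test_that("oversized shapes are rejected with a geometry error", {
  expect_error(generatePhantom(phantomSpec("bladder_full",
                                           semiAxesMm = c(40, 40, 90))),
               class = "contourQA_geometry_error")
})

test_that("missing interior slices break both contiguity checks", {
  cord <- generatePhantom(phantomSpec("spinal_cord", seed = 4))
  inj <- injectDefect(cord, defectSpec("missing_slices"))
  expect_identical(inj$label, "defect:missing_slices")
  expect_setequal(inj$expectedDetectors, c("extent", "region_growing"))
  expect_false(isContiguous(checkExtentContiguity(inj$mask)))
  expect_false(isContiguous(checkRegionGrowingContiguity(inj$mask)))
  # verified against the oracle on a small rendition
  smallCord <- generatePhantom(phantomSpec(
    "spinal_cord", grid = VoxelGrid(c(10, 10, 20), c(4, 4, 8)),
    radiusMm = 6, driftAmpMm = c(2, 2), zMarginSlices = 2, seed = 3))
  injS <- injectDefect(smallCord, defectSpec("missing_slices"))
  expect_gt(verdictDetail(connectedComponentsOracle(injS$mask))$component_count, 1L)

  # deleting a boundary slice is not an interior gap and is refused
  zs <- sort(unique(voxelIndices(cord)[, "z"]))
  expect_error(injectDefect(cord, defectSpec("missing_slices",
                                             sliceIndices = zs[1])),
               class = "contourQA_validation_error")
})

test_that("a detached island defeats region growing but not the extent check", {
  sphere <- generatePhantom(phantomSpec("bladder_full", seed = 8))
  inj <- injectDefect(sphere, defectSpec("detached_island"))
  expect_identical(inj$expectedDetectors, "region_growing")
  expect_true(isContiguous(checkExtentContiguity(inj$mask)))
  v <- checkRegionGrowingContiguity(inj$mask)
  expect_false(isContiguous(v))
  # whichever side the seed lands on, the other component is the 2^3 island
  expect_equal(min(verdictDetail(v)$visited_count,
                   verdictDetail(v)$total_count - verdictDetail(v)$visited_count),
               8L)

  smallSphere <- smallSpherePhantom(radiusVox = 6, dims = c(17, 17, 17))
  injS <- injectDefect(smallSphere, defectSpec("detached_island"))
  oc <- verdictDetail(connectedComponentsOracle(injS$mask))
  expect_equal(oc$component_count, 2L)
  expect_true(isContiguous(checkExtentContiguity(injS$mask)))
})

test_that("a frame shift inflates slice extents without breaking contiguity", {
  cord <- generatePhantom(phantomSpec("spinal_cord", seed = 6))
  before <- sliceExtents(cord)
  inj <- injectDefect(cord, defectSpec("frame_shift"))
  expect_true(isContiguous(checkExtentContiguity(inj$mask)))
  expect_true(isContiguous(checkRegionGrowingContiguity(inj$mask)))
  after <- sliceExtents(inj$mask)
  expect_gte(after$lr_range_of_ranges_mm, before$lr_range_of_ranges_mm + 4)
  expect_gte(after$ap_range_of_ranges_mm, before$ap_range_of_ranges_mm + 4)
})

test_that("interior voids and oblong slices behave as designed", {
  b <- generatePhantom(phantomSpec("bladder_full", seed = 9))
  void <- injectDefect(b, defectSpec("interior_void"))
  expect_identical(void$expectedDetectors, character(0))
  expect_true(isContiguous(checkRegionGrowingContiguity(void$mask)))
  expect_lt(computeVolume(void$mask), computeVolume(b))

  cord <- generatePhantom(phantomSpec("spinal_cord", seed = 10))
  ob <- injectDefect(cord, defectSpec("slice_oblong"))
  expect_true(isContiguous(checkRegionGrowingContiguity(ob$mask)))
  expect_gte(sliceExtents(ob$mask)$lr_range_of_ranges_mm,
             sliceExtents(cord)$lr_range_of_ranges_mm + 4)
})

test_that("cohort generation is labelled, counted and byte-reproducible", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  man1 <- generateCohort("spinal_cord", 20, 0.1, seed = 7, outDir = d1)
  expect_equal(sum(man1$ground_truth_label != "clean"), 2L)
  man2 <- generateCohort("spinal_cord", 20, 0.1, seed = 7, outDir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "manifest.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  # defect-free cohorts pass both contiguity checks everywhere
  d3 <- withr::local_tempdir()
  man3 <- generateCohort("spinal_cord", 10, 0, seed = 9, outDir = d3)
  for (p in man3$mask_path) {
    m <- readMask(p)
    expect_true(isContiguous(checkExtentContiguity(m)))
    expect_true(isContiguous(checkRegionGrowingContiguity(m)))
  }

  expect_error(generateCohort("rectum", 5, 0, seed = 1,
                              outDir = withr::local_tempdir()),
               class = "contourQA_validation_error")
  expect_error(generateCohort("rectum", 10, 0.5, seed = 1,
                              defectMix = c(nonsense = 1),
                              outDir = withr::local_tempdir()),
               class = "contourQA_validation_error")
})
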