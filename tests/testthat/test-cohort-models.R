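test_that("cohortPercentile interpolates linearly between closest ranks", {
  expect_equal(cohortPercentile(c(1, 2, 3), 50), 2)
  expect_equal(cohortPercentile(c(0, 10), 25), 2.5)
  set.seed(1)
  v <- stats::rnorm(37)
  expect_equal(cohortPercentile(v, 100), max(v))
  expect_equal(cohortPercentile(v, 0), min(v))
  expect_equal(cohortPercentile(sample(v), 37.5), cohortPercentile(v, 37.5))
  expect_error(cohortPercentile(numeric(0), 50),
               class = "contourQA_validation_error")
})

# the standard synthetic bladder cohort: clean full bladders from the three
# size classes, optionally with planted empty-bladder rows at the end
bladderCohort <- function(nClean = 45, nEmpty = 5, seed = 11) {
  withr::with_seed(seed, {
    masks <- c(
      lapply(seq_len(nClean), function(i)
        generatePhantom(phantomSpec("bladder_full", seed = seed + i,
                                    scale = sample(c(20, 24, 28) / 24, 1)))),
      lapply(seq_len(nEmpty), function(i)
        generatePhantom(phantomSpec("bladder_empty", seed = seed + nClean + i,
                                    scale = sample(c(20, 24, 28) / 24, 1)))))
    cohortFeatures(masks)
  })
}

test_that("bladder model flags low-volume extreme-ratio rows only", {
  # identical spheres: nobody is strictly below Q1 with an extreme ratio
  same <- cohortFeatures(lapply(1:10, function(i)
    generatePhantom(phantomSpec("bladder_full", seed = i))))
  expect_equal(sum(bladderModel(same)$flagged), 0L)

  feats <- bladderCohort(45, 5)
  res <- bladderModel(feats)
  expect_equal(which(res$flagged), 46:50)
  thr <- attr(res, "thresholds")
  expect_equal(thr$volume_mm3, cohortPercentile(feats$volume_mm3, 25))

  # low-volume but shape-typical rows must fail the AND gate
  cleanOnly <- bladderCohort(45, 0)
  expect_equal(sum(bladderModel(cleanOnly)$flagged), 0L)

  expect_error(bladderModel(feats[1:5, ]),
               class = "contourQA_cohort_size_error")
})

test_that("bladder model auto-flags undefined ratios in the bottom quartile", {
  feats <- bladderCohort(45, 0)
  degenerate <- cohortFeatures(list(
    maskFromVoxels(list(c(1, 1, 1)), c(4, 4, 4))), "P9999", "bladder")
  res <- bladderModel(rbind(feats, degenerate))
  expect_true(res$flagged[res$patient_id == "P9999"])
})

femoralCohort <- function(nBall = 30, nShaft = 20, seed = 5) {
  withr::with_seed(seed, {
    masks <- c(
      lapply(seq_len(nBall), function(i)
        generatePhantom(phantomSpec("femoral_ball", seed = seed + i,
                                    scale = stats::runif(1, 0.95, 1.05)))),
      lapply(seq_len(nShaft), function(i)
        generatePhantom(phantomSpec("femoral_ball_shaft",
                                    seed = seed + nBall + i,
                                    scale = stats::runif(1, 0.95, 1.05)))))
    cohortFeatures(masks)
  })
}

test_that("femoral model separates ball-only from ball+shaft contours", {
  ballsOnly <- femoralCohort(12, 0)
  expect_true(all(femoralHeadModel(ballsOnly)$classification == "ball_only"))

  feats <- femoralCohort(30, 20)
  res <- femoralHeadModel(feats)
  expect_equal(which(res$classification == "ball_shaft"), 31:50)

  # a composite contour with too little head volume fails the volume gate
  small <- cohortFeatures(list(
    generatePhantom(phantomSpec("femoral_ball_shaft", seed = 99,
                                scale = 0.8))), "P9999", "femoral_head_left")
  res2 <- femoralHeadModel(rbind(feats, small))
  row <- res2[res2$patient_id == "P9999", ]
  expect_false(row$volume_above_gate)
  expect_equal(row$classification, "ball_only")

  expect_error(femoralHeadModel(feats[1:4, ]),
               class = "contourQA_cohort_size_error")
})

cordCohort <- function(nClean = 49, defect = NULL, seed = 21) {
  masks <- lapply(seq_len(nClean), function(i)
    generatePhantom(phantomSpec("spinal_cord", seed = seed + i)))
  if (!is.null(defect)) {
    m <- generatePhantom(phantomSpec("spinal_cord", seed = seed + nClean + 1))
    masks <- c(masks, list(injectDefect(m, defect)$mask))
  }
  cohortFeatures(masks)
}

test_that("slice-extent model flags abnormal per-slice extent spread", {
  feats <- cordCohort(49, defectSpec("frame_shift"))
  res <- sliceExtentModel(feats)
  expect_equal(which(res$flagged), 50L)

  clean <- cordCohort(12)
  expect_equal(sum(sliceExtentModel(clean)$flagged), 0L)
})

test_that("slice-extent AND/OR combination controls one-direction bulges", {
  feats <- cordCohort(20)
  # an LR-only bulge: widen one slice along x only
  m <- generatePhantom(phantomSpec("spinal_cord", seed = 99))
  a <- maskArray(m)
  zs <- sort(unique(voxelIndices(m)[, "z"]))
  z <- zs[10] + 1L
  sl <- a[, , z]
  for (dx in 1:8) {
    shifted <- rbind(sl[-seq_len(dx), ], matrix(0L, dx, ncol(sl)))
    sl <- pmax(sl, shifted)
  }
  a[, , z] <- sl
  bulged <- cohortFeatures(list(StructureMask(a, maskGrid(m))),
                           "P9999", "spinal_cord")
  both <- rbind(feats, bulged)
  expect_false(sliceExtentModel(both, modelConfig())$flagged[21])
  expect_true(sliceExtentModel(
    both, modelConfig(sliceExtentCombine = "or"))$flagged[21])
})

test_that("flags are a pure function of features and config", {
  feats <- bladderCohort(20, 2, seed = 31)
  res <- bladderModel(feats)
  perm <- withr::with_seed(1, sample(nrow(feats)))
  resPerm <- bladderModel(feats[perm, ])
  expect_equal(resPerm$flagged[order(perm)], res$flagged)
})

test_that("uniform spacing rescaling leaves percentile flags unchanged", {
  set.seed(61)
  masks <- c(lapply(1:18, function(i)
    generatePhantom(phantomSpec("bladder_full", seed = i,
                                scale = sample(c(20, 24, 28) / 24, 1)))),
    lapply(19:20, function(i)
      generatePhantom(phantomSpec("bladder_empty", seed = i))))
  feats1 <- cohortFeatures(masks)
  rescaled <- lapply(masks, function(m) {
    g <- maskGrid(m)
    StructureMask(rleTransitions(m), VoxelGrid(gridDims(g),
                                               2 * gridSpacing(g)),
                  roiName = roiName(m))
  })
  feats2 <- cohortFeatures(rescaled)
  expect_equal(feats2$volume_mm3, 8 * feats1$volume_mm3)
  expect_equal(feats2$lr_over_is, feats1$lr_over_is)
  expect_equal(bladderModel(feats2)$flagged, bladderModel(feats1)$flagged)
  expect_equal(sliceExtentModel(feats2)$flagged,
               sliceExtentModel(feats1)$flagged)
})
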