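# ---- synthetic organ phantoms and defect injection ----------------------
# Deterministic, seeded generators of organ-shaped binary masks on
# clinically plausible anisotropic grids, plus injectors for the defect
# classes the integrity checks are meant to catch. All phantoms are
# 26-connected by construction before injection.

.ORGANS <- c("bladder_full", "bladder_empty", "femoral_ball",
             "femoral_ball_shaft", "spinal_cord", "rectum", "prostate",
             "brainstem_like")
.DEFECT_KINDS <- c("missing_slices", "detached_island", "frame_shift",
                   "interior_void", "slice_oblong")
.PRNG <- "Mersenne-Twister"

.defaultGrid <- function(organ) {
  if (organ == "spinal_cord") VoxelGrid(c(32, 32, 120), c(1, 1, 2))
  else VoxelGrid(c(64, 64, 80), c(1, 1, 2))
}

# organ -> manifest roi_name vocabulary
.organRoiName <- function(organ) {
  switch(organ,
         bladder_full = , bladder_empty = "bladder",
         femoral_ball = , femoral_ball_shaft = "femoral_head_left",
         brainstem_like = "brainstem",
         organ)
}

.defaultParams <- function(organ) {
  switch(organ,
    bladder_full = list(semiAxesMm = c(24, 24, 24), scale = 1),
    bladder_empty = list(semiAxesMm = c(20, 14, 6), scale = 1),
    femoral_ball = list(semiAxesMm = c(24, 18, 20), scale = 1),
    femoral_ball_shaft = list(ballRadiusMm = 16, shaftRadiusMm = 10,
                              shaftLengthMm = 96, scale = 1),
    spinal_cord = list(radiusMm = 5, driftAmpMm = c(2, 2),
                       driftWavelengthMm = 150, driftPhase = NULL,
                       zMarginSlices = 5),
    rectum = list(radiusMm = 14, curveAmpMm = 9, lengthSlices = 40),
    prostate = list(semiAxesMm = c(20, 16, 18), scale = 1),
    brainstem_like = list(radiusTopMm = 12, radiusBottomMm = 7,
                          lengthSlices = 30))
}

#' Specify a synthetic organ phantom
#'
#' @param organ one of \code{bladder_full}, \code{bladder_empty},
#'   \code{femoral_ball}, \code{femoral_ball_shaft}, \code{spinal_cord},
#'   \code{rectum}, \code{prostate}, \code{brainstem_like}.
#' @param grid a [VoxelGrid-class]; defaults to 64x64x80 voxels at
#'   1x1x2 mm (32x32x120 for spinal cords).
#' @param seed integer seed for any shape parameter left unspecified (e.g.
#'   the cord drift phase); generation is fully deterministic given the spec.
#' @param ... organ-specific shape parameters overriding the defaults
#'   (semi-axes, radii and lengths in mm; dimensionless \code{scale}).
#' @return a list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(organ, grid = NULL, seed = 1L, ...) {
  organ <- match.arg(organ, .ORGANS)
  if (is.null(grid)) grid <- .defaultGrid(organ)
  params <- .defaultParams(organ)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    .validationError("unknown parameter(s) for organ '%s': %s", organ,
                     paste(unknown, collapse = ", "))
  params[names(dots)] <- dots
  structure(list(organ = organ, grid = grid, seed = as.integer(seed),
                 params = params), class = "phantomSpec")
}

.physCoords <- function(grid) {
  d <- grid@dims; sp <- grid@spacing
  list(x = (seq_len(d[1L]) - 1) * sp[1L],
       y = (seq_len(d[2L]) - 1) * sp[2L],
       z = (seq_len(d[3L]) - 1) * sp[3L],
       center = (d - 1) * sp / 2)
}

.ellipsoidArray <- function(grid, semi, center) {
  co <- .physCoords(grid)
  ex <- ((co$x - center[1L]) / semi[1L])^2
  ey <- ((co$y - center[2L]) / semi[2L])^2
  ez <- ((co$z - center[3L]) / semi[3L])^2
  array(as.integer(outer(outer(ex, ey, "+"), ez, "+") <= 1), dim = grid@dims)
}

# tube along z: per-slice disk with slice-dependent centre and radius
.tubeArray <- function(grid, zSlices, cx, cy, radius) {
  co <- .physCoords(grid)
  arr <- array(0L, dim = grid@dims)
  for (k in seq_along(zSlices)) {
    d2 <- outer((co$x - cx[k])^2, (co$y - cy[k])^2, "+")
    arr[, , zSlices[k] + 1L] <- as.integer(d2 <= radius[k]^2)
  }
  arr
}

#' Generate a synthetic organ phantom mask
#'
#' Deterministic given the spec (including its seed). Bladders are
#' ellipsoids (full: near-spherical; empty: a flattened low-volume shell
#' shape); femoral balls are head+neck-like ellipsoids elongated laterally;
#' \code{femoral_ball_shaft} is a sphere with an abutting inferior cylinder;
#' spinal cords are long thin inferior-superior tubes with smooth sinusoidal
#' lateral drift; rectums are curved tubes; brainstem-like shapes are
#' tapered tubes. The generated mask is non-empty, 26-connected, and keeps
#' at least one voxel of margin to the grid boundary.
#'
#' @param spec a [phantomSpec()].
#' @return a [StructureMask-class] with \code{roiName} set to the manifest
#'   vocabulary name of the organ.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  grid <- spec$grid; p <- spec$params
  co <- .physCoords(grid)
  arr <- switch(spec$organ,
    bladder_full = ,
    bladder_empty = ,
    prostate = ,
    femoral_ball =
      .ellipsoidArray(grid, p$semiAxesMm * p$scale, co$center),
    femoral_ball_shaft = {
      r <- p$ballRadiusMm * p$scale
      shaftLen <- p$shaftLengthMm * p$scale
      shaftR <- p$shaftRadiusMm * p$scale
      zTop <- co$center[3L] + (r + shaftLen) / 2  # ball centre
      ball <- .ellipsoidArray(grid, c(r, r, r),
                              c(co$center[1L], co$center[2L], zTop))
      zBot <- zTop - shaftLen
      zSl <- which(co$z >= zBot & co$z <= zTop) - 1L
      shaft <- .tubeArray(grid, zSl,
                          rep(co$center[1L], length(zSl)),
                          rep(co$center[2L], length(zSl)),
                          rep(shaftR, length(zSl)))
      pmax(ball, shaft)
    },
    spinal_cord = {
      phase <- p$driftPhase
      if (is.null(phase))
        phase <- withr::with_seed(spec$seed,
                                  stats::runif(2, 0, 2 * pi),
                                  .rng_kind = .PRNG)
      zSl <- seq.int(p$zMarginSlices, grid@dims[3L] - 1L - p$zMarginSlices)
      zMm <- zSl * grid@spacing[3L]
      cx <- co$center[1L] +
        p$driftAmpMm[1L] * sin(2 * pi * zMm / p$driftWavelengthMm + phase[1L])
      cy <- co$center[2L] +
        p$driftAmpMm[2L] * sin(2 * pi * zMm / p$driftWavelengthMm + phase[2L])
      .tubeArray(grid, zSl, cx, cy, rep(p$radiusMm, length(zSl)))
    },
    rectum = {
      n <- p$lengthSlices
      z0 <- (grid@dims[3L] - n) %/% 2L
      zSl <- seq.int(z0, z0 + n - 1L)
      t <- seq(0, pi, length.out = n)
      cy <- co$center[2L] + p$curveAmpMm * sin(t)   # sacral curve
      cx <- rep(co$center[1L], n)
      .tubeArray(grid, zSl, cx, cy, rep(p$radiusMm, n))
    },
    brainstem_like = {
      n <- p$lengthSlices
      z0 <- (grid@dims[3L] - n) %/% 2L
      zSl <- seq.int(z0, z0 + n - 1L)
      rr <- seq(p$radiusBottomMm, p$radiusTopMm, length.out = n)
      .tubeArray(grid, zSl, rep(co$center[1L], n), rep(co$center[2L], n), rr)
    })
  mask <- StructureMask(arr, grid, roiName = .organRoiName(spec$organ))
  if (voxelCount(mask) == 0L)
    .geometryError("phantom '%s' produced an empty mask", spec$organ)
  ext <- computeExtent(mask)
  if (any(ext$min_index < 1L) || any(ext$max_index > grid@dims - 2L))
    .geometryError("phantom '%s' does not fit inside the grid with a 1-voxel margin",
                   spec$organ)
  mask
}

#' Specify a planted contour defect
#'
#' @param kind one of \code{missing_slices} (delete whole slices along an
#'   axis), \code{detached_island} (add a small voxel island separated from
#'   the body by more than the neighbour radius), \code{frame_shift}
#'   (displace one slice's contour in-plane; the displaced copy coexists
#'   with the original slice content, as when a shifted contour overlays
#'   interpolated anatomy, so slice extents inflate while contiguity is
#'   preserved), \code{interior_void} (carve an interior cavity), or
#'   \code{slice_oblong} (dilate one slice in-plane).
#' @param seed integer seed for any placement left unspecified.
#' @param ... kind-specific parameters: \code{axis}/\code{sliceIndices}
#'   (missing_slices), \code{islandSize} (detached_island),
#'   \code{sliceIndex}/\code{shiftVoxels} (frame_shift),
#'   \code{voidSize} (interior_void), \code{sliceIndex}/\code{dilateVoxels}
#'   (slice_oblong).
#' @return a list of class \code{defectSpec}.
#' @export
defectSpec <- function(kind, seed = 1L, ...) {
  kind <- match.arg(kind, .DEFECT_KINDS)
  defaults <- switch(kind,
    missing_slices = list(axis = "is", sliceIndices = NULL),
    detached_island = list(islandSize = 2L),
    frame_shift = list(sliceIndex = NULL, shiftVoxels = c(6L, 6L)),
    interior_void = list(voidSize = 3L),
    slice_oblong = list(sliceIndex = NULL, dilateVoxels = 3L))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    .validationError("unknown parameter(s) for defect '%s': %s", kind,
                     paste(unknown, collapse = ", "))
  defaults[names(dots)] <- dots
  structure(c(list(kind = kind, seed = as.integer(seed)), defaults),
            class = "defectSpec")
}

# middle occupied z-slice (0-based)
.middleOccupiedSlice <- function(mask) {
  zs <- sort(unique(voxelIndices(mask)[, "z"]))
  zs[ceiling(length(zs) / 2)]
}

.injectMissingSlices <- function(arr, mask, d) {
  axis <- match.arg(d$axis, c("lr", "ap", "is"))
  ax <- match(axis, c("lr", "ap", "is"))
  idx <- d$sliceIndices
  occ <- sort(unique(voxelIndices(mask)[, ax]))
  if (is.null(idx)) idx <- occ[ceiling(length(occ) / 2)]
  if (!all(idx %in% occ))
    .validationError("missing_slices: slice index(es) %s are not occupied",
                     paste(setdiff(idx, occ), collapse = ", "))
  if (any(idx == occ[1L]) || any(idx == occ[length(occ)]))
    .validationError("missing_slices: refuse to delete a boundary slice (would not be an interior gap)")
  switch(ax, arr[idx + 1L, , ] <- 0L, arr[, idx + 1L, ] <- 0L,
         arr[, , idx + 1L] <- 0L)
  list(arr = arr, expected = c("extent", "region_growing"))
}

.injectDetachedIsland <- function(arr, mask, d) {
  dims <- dim(arr)
  sz <- as.integer(d$islandSize)
  ext <- computeExtent(mask)
  lo <- ext$min_index; hi <- ext$max_index
  corners <- as.matrix(expand.grid(x = c(lo[1L], hi[1L] - sz + 1L),
                                   y = c(lo[2L], hi[2L] - sz + 1L),
                                   z = c(lo[3L], hi[3L] - sz + 1L)))
  body <- voxelIndices(mask)
  for (k in seq_len(nrow(corners))) {
    c0 <- corners[k, ]
    if (any(c0 < 0L) || any(c0 + sz > dims)) next
    # require an exact Euclidean gap of >= 2 voxels (> sqrt(3)) between
    # every island voxel and every body voxel
    isl <- as.matrix(expand.grid(x = c0[1L] + 0:(sz - 1L),
                                 y = c0[2L] + 0:(sz - 1L),
                                 z = c0[3L] + 0:(sz - 1L)))
    d2min <- min(vapply(seq_len(nrow(isl)), function(j)
      min((body[, 1L] - isl[j, 1L])^2 + (body[, 2L] - isl[j, 2L])^2 +
            (body[, 3L] - isl[j, 3L])^2), numeric(1)))
    if (d2min < 4) next
    arr[(c0[1L]:(c0[1L] + sz - 1L)) + 1L,
        (c0[2L]:(c0[2L] + sz - 1L)) + 1L,
        (c0[3L]:(c0[3L] + sz - 1L)) + 1L] <- 1L
    # placement inside the body's bounding box keeps every axis projection
    # complete, so only region growing is expected to fire
    return(list(arr = arr, expected = "region_growing"))
  }
  .validationError("detached_island: no bounding-box corner admits an island of size %d with a >sqrt(3) gap", sz)
}

.injectFrameShift <- function(arr, mask, d) {
  dims <- dim(arr)
  z <- d$sliceIndex
  if (is.null(z)) z <- .middleOccupiedSlice(mask)
  sl <- arr[, , z + 1L]
  if (all(sl == 0L))
    .validationError("frame_shift: slice %d is not occupied", z)
  sh <- as.integer(d$shiftVoxels)
  shifted <- matrix(0L, dims[1L], dims[2L])
  xs <- which(sl != 0L, arr.ind = TRUE)
  nx <- xs[, 1L] + sh[1L]; ny <- xs[, 2L] + sh[2L]
  ok <- nx >= 1L & nx <= dims[1L] & ny >= 1L & ny <= dims[2L]
  if (!any(ok))
    .validationError("frame_shift: shift (%d, %d) pushes the whole slice off the grid", sh[1L], sh[2L])
  shifted[cbind(nx[ok], ny[ok])] <- 1L
  arr[, , z + 1L] <- pmax(sl, shifted)
  list(arr = arr, expected = "slice_extent")
}

.injectInteriorVoid <- function(arr, mask, d) {
  sz <- as.integer(d$voidSize)
  xyz <- voxelIndices(mask)
  ctr <- round(colMeans(xyz))
  c0 <- ctr - sz %/% 2L
  rng <- lapply(1:3, function(a) (c0[a]:(c0[a] + sz - 1L)) + 1L)
  cube <- arr[rng[[1L]], rng[[2L]], rng[[3L]]]
  if (any(cube == 0L))
    .validationError("interior_void: the centroid cube is not fully interior to the mask")
  arr[rng[[1L]], rng[[2L]], rng[[3L]]] <- 0L
  list(arr = arr, expected = character(0))
}

.injectSliceOblong <- function(arr, mask, d) {
  dims <- dim(arr)
  z <- d$sliceIndex
  if (is.null(z)) z <- .middleOccupiedSlice(mask)
  k <- as.integer(d$dilateVoxels)
  sl <- arr[, , z + 1L]
  if (all(sl == 0L))
    .validationError("slice_oblong: slice %d is not occupied", z)
  out <- matrix(0L, dims[1L], dims[2L])
  xs <- which(sl != 0L, arr.ind = TRUE)
  for (dx in -k:k) for (dy in -k:k) {
    nx <- xs[, 1L] + dx; ny <- xs[, 2L] + dy
    ok <- nx >= 1L & nx <= dims[1L] & ny >= 1L & ny <= dims[2L]
    out[cbind(nx[ok], ny[ok])] <- 1L
  }
  arr[, , z + 1L] <- out
  list(arr = arr, expected = "slice_extent")
}

#' Inject a planted defect into a mask
#'
#' @param mask a [StructureMask-class].
#' @param defect a [defectSpec()].
#' @return a list with \code{mask} (the defective [StructureMask-class]),
#'   \code{label} (\code{"defect:<kind>"}), and \code{expectedDetectors}
#'   (which detectors the construction guarantees will fire:
#'   \code{extent}, \code{region_growing}, \code{slice_extent}; empty for a
#'   defect designed to be invisible to the contiguity checks).
#' @export
injectDefect <- function(mask, defect) {
  stopifnot(inherits(defect, "defectSpec"))
  if (voxelCount(mask) == 0L) .emptyMaskError("injectDefect")
  arr <- maskArray(mask)
  res <- switch(defect$kind,
                missing_slices = .injectMissingSlices(arr, mask, defect),
                detached_island = .injectDetachedIsland(arr, mask, defect),
                frame_shift = .injectFrameShift(arr, mask, defect),
                interior_void = .injectInteriorVoid(arr, mask, defect),
                slice_oblong = .injectSliceOblong(arr, mask, defect))
  out <- StructureMask(res$arr, mask@grid, roiName = mask@roiName)
  if (identical(out@transitions, mask@transitions))
    .validationError("defect '%s' left the mask unchanged", defect$kind)
  list(mask = out, label = paste0("defect:", defect$kind),
       expectedDetectors = res$expected)
}

# per-organ shape-parameter jitter (recorded in the manifest header).
# Bladders are drawn from three discrete size classes (semi-axis 20/24/28 mm
# at the default 24): full bladders share one shape, so their extent ratios
# are tied up to voxel quantization and the cohort percentile gates bind
# only on genuinely extreme shapes.
.BLADDER_CLASSES <- c(20, 24, 28) / 24

.jitterRanges <- function(organ) {
  switch(organ,
    bladder_full = , bladder_empty = list(scale = c(0.833, 1.167)),
    femoral_ball = , femoral_ball_shaft = list(scale = c(0.95, 1.05)),
    spinal_cord = list(driftAmpMm = c(1, 3),
                       driftWavelengthMm = c(120, 180)),
    rectum = list(curveAmpMm = c(6, 12)),
    prostate = , brainstem_like = list(scale = c(0.9, 1.1)))
}

.drawJitter <- function(organ) {
  jr <- .jitterRanges(organ)
  if (organ %in% c("bladder_full", "bladder_empty"))
    list(scale = sample(.BLADDER_CLASSES, 1L))
  else if (organ == "spinal_cord")
    list(driftAmpMm = stats::runif(2, jr$driftAmpMm[1], jr$driftAmpMm[2]),
         driftWavelengthMm = stats::runif(1, jr$driftWavelengthMm[1],
                                          jr$driftWavelengthMm[2]),
         driftPhase = stats::runif(2, 0, 2 * pi))
  else if (organ == "rectum")
    list(curveAmpMm = stats::runif(1, jr$curveAmpMm[1], jr$curveAmpMm[2]))
  else
    list(scale = stats::runif(1, jr$scale[1], jr$scale[2]))
}

#' Generate a labelled synthetic cohort on disk
#'
#' Writes \code{n} phantom masks of one organ, a configurable fraction of
#' which carry planted defects, plus a cohort manifest CSV whose header
#' comments record the generator, PRNG, seed and jitter ranges. Everything
#' is deterministic given the arguments: two calls with the same arguments
#' produce identical manifests and mask files.
#'
#' @param organ phantom organ name (see [phantomSpec()]).
#' @param n cohort size, at least 10.
#' @param defectFraction fraction of rows receiving a defect (rounded to a
#'   whole number of rows).
#' @param defectMix named numeric vector of weights over defect kinds.
#' @param seed master integer seed.
#' @param outDir output directory (created if needed).
#' @param format \code{"rle_json"} (default) or \code{"nifti"}.
#' @return the manifest data.frame (with absolute \code{mask_path}),
#'   invisibly; also written to \code{file.path(outDir, "manifest.csv")}.
#' @export
generateCohort <- function(organ, n, defectFraction = 0.1,
                           defectMix = c(missing_slices = 0.5,
                                         detached_island = 0.5),
                           seed = 1L, outDir,
                           format = c("rle_json", "nifti")) {
  organ <- match.arg(organ, .ORGANS)
  format <- match.arg(format)
  if (n < 10L) .validationError("cohort size must be at least 10, got %d", n)
  if (defectFraction < 0 || defectFraction > 1)
    .validationError("defectFraction must lie in [0, 1]")
  nDefect <- round(n * defectFraction)
  if (nDefect > 0L) {
    if (!length(defectMix) || any(defectMix < 0) || sum(defectMix) <= 0 ||
        !all(names(defectMix) %in% .DEFECT_KINDS))
      .validationError("defectMix must be nonnegative weights over known defect kinds")
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  ext <- if (format == "rle_json") ".rle.json" else ".nii.gz"
  roi <- .organRoiName(organ)

  rows <- withr::with_seed(seed, .rng_kind = .PRNG, {
    defectRows <- if (nDefect > 0L) sort(sample.int(n, nDefect)) else integer(0)
    kinds <- if (nDefect > 0L)
      sample(names(defectMix), nDefect, replace = TRUE,
             prob = defectMix / sum(defectMix)) else character(0)
    lapply(seq_len(n), function(i) {
      jit <- .drawJitter(organ)
      list(i = i, jitter = jit,
           defect = if (i %in% defectRows) kinds[match(i, defectRows)]
                    else NA_character_)
    })
  })

  manifest <- do.call(rbind, lapply(rows, function(r) {
    spec <- do.call(phantomSpec,
                    c(list(organ = organ, seed = .deriveSeed(seed, r$i)),
                      r$jitter))
    mask <- generatePhantom(spec)
    if (!is.na(r$defect)) {
      inj <- injectDefect(mask,
                          defectSpec(r$defect, seed = .deriveSeed(seed, r$i)))
      mask <- inj$mask
      label <- inj$label
    } else label <- "clean"
    fname <- sprintf("%s_%04d%s", organ, r$i, ext)
    writeMask(mask, file.path(outDir, fname), format = format)
    data.frame(patient_id = sprintf("P%04d", r$i), roi_name = roi,
               mask_path = fname, ground_truth_label = label)
  }))

  header <- c(
    "generator: contourQA synthetic phantom cohort v1",
    paste0("prng: ", .PRNG),
    paste0("seed: ", seed),
    paste0("organ: ", organ),
    paste0("defect_fraction: ", defectFraction),
    paste0("jitter: ", if (organ %in% c("bladder_full", "bladder_empty"))
      sprintf("scale~{%s} (discrete size classes)",
              paste(round(.BLADDER_CLASSES, 3), collapse = ","))
    else paste(vapply(names(.jitterRanges(organ)), function(nm) {
      r <- .jitterRanges(organ)[[nm]]
      sprintf("%s~U(%g,%g)", nm, r[1], r[2])
    }, character(1)), collapse = "; ")))
  writeManifest(manifest, file.path(outDir, "manifest.csv"),
                headerLines = header)
  manifest$mask_path <- file.path(normalizePath(outDir), manifest$mask_path)
  invisible(manifest)
}

#' Detectors expected to fire for a ground-truth defect kind
#'
#' Maps a manifest ground-truth label to the set of detectors that should
#' flag it: missing slices break both contiguity checks; a detached island
#' breaks only region growing (when placed inside the bounding box);
#' frame shifts and oblong slices are slice-extent outliers; an empty
#' bladder plant is the bladder model's target; an interior void is
#' invisible to all the geometric detectors.
#'
#' @param label ground-truth label vector (\code{"clean"} or
#'   \code{"defect:<kind>"}).
#' @return a list (one element per label) of detector name vectors, subsets
#'   of \code{c("extent", "region_growing", "slice_extent", "bladder")}.
#' @export
expectedDetectors <- function(label) {
  lapply(label, function(l) {
    if (is.na(l) || l %in% c("", "clean")) return(character(0))
    kind <- sub("^defect:", "", l)
    switch(kind,
           missing_slices = c("extent", "region_growing"),
           detached_island = "region_growing",
           frame_shift = , slice_oblong = "slice_extent",
           empty_bladder = "bladder",
           interior_void = character(0),
           character(0))
  })
}
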