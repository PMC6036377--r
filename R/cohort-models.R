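# ---- cohort feature table and percentile-threshold models ---------------

#' Linear-interpolation percentile
#'
#' Percentile by linear interpolation between closest ranks: the minimum sits
#' at rank 0 and the maximum at rank n-1 (the type-7 quantile definition),
#' so \code{p = 0} returns the minimum, \code{p = 100} the maximum, and the
#' result is invariant under permutation of the input.
#'
#' @param values non-empty numeric vector (NAs are rejected).
#' @param p percentile in \code{[0, 100]}.
#' @return the interpolated percentile value.
#' @examples
#' cohortPercentile(c(1, 2, 3), 50)  # 2
#' cohortPercentile(c(0, 10), 25)    # 2.5
#' @export
cohortPercentile <- function(values, p) {
  if (length(values) == 0L)
    .validationError("cannot take a percentile of an empty vector")
  if (anyNA(values))
    .validationError("percentile input contains NA")
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 100)
    .validationError("p must be a single number in [0, 100]")
  unname(stats::quantile(values, probs = p / 100, type = 7, names = FALSE))
}

#' Cohort model configuration
#'
#' Default thresholds for the three percentile models. The bladder model
#' gates on the bottom volume quartile and extreme extent ratios
#' (below the 10th / above the 90th cohort percentile). The femoral-head
#' model gates on volume above the 20th percentile, then classifies
#' ball+shaft by a long inferior-superior extent and a near-symmetric
#' lateral/anterior-posterior ratio; its two numeric thresholds are
#' calibration constants (defaults fitted once on the synthetic phantom
#' cohorts). The slice-extent model flags rows whose per-slice extent
#' range-of-ranges exceeds the cohort 90th percentile in the LR and AP
#' directions, combined with AND (or OR).
#'
#' @param bladderVolumePercentile volume gate percentile (default 25).
#' @param bladderRatioLowPercentile,bladderRatioHighPercentile extreme-ratio
#'   percentiles (defaults 10 and 90).
#' @param femoralVolumePercentile volume gate percentile (default 20).
#' @param femoralIsRangeMmThreshold inferior-superior extent (mm) above
#'   which a shaft is suspected (default 100).
#' @param femoralLrOverApRatioThreshold lateral/AP ratio below which the
#'   contour is too symmetric for a head+neck-only contour (default 1.15).
#' @param sliceExtentPercentile slice range-of-ranges percentile (default 90).
#' @param sliceExtentCombine \code{"and"} or \code{"or"} over the LR and AP
#'   exceedances (default \code{"and"}).
#' @param minCohortRows floor below which percentile models refuse to run
#'   (default 8).
#' @return a list of class \code{modelConfig}.
#' @export
modelConfig <- function(bladderVolumePercentile = 25,
                        bladderRatioLowPercentile = 10,
                        bladderRatioHighPercentile = 90,
                        femoralVolumePercentile = 20,
                        femoralIsRangeMmThreshold = 100,
                        femoralLrOverApRatioThreshold = 1.15,
                        sliceExtentPercentile = 90,
                        sliceExtentCombine = c("and", "or"),
                        minCohortRows = 8L) {
  pcts <- c(bladderVolumePercentile, bladderRatioLowPercentile,
            bladderRatioHighPercentile, femoralVolumePercentile,
            sliceExtentPercentile)
  if (any(pcts <= 0 | pcts >= 100))
    .validationError("all percentiles must lie strictly between 0 and 100")
  if (femoralIsRangeMmThreshold <= 0 || femoralLrOverApRatioThreshold <= 0)
    .validationError("femoral thresholds must be positive")
  structure(list(
    bladderVolumePercentile = bladderVolumePercentile,
    bladderRatioLowPercentile = bladderRatioLowPercentile,
    bladderRatioHighPercentile = bladderRatioHighPercentile,
    femoralVolumePercentile = femoralVolumePercentile,
    femoralIsRangeMmThreshold = femoralIsRangeMmThreshold,
    femoralLrOverApRatioThreshold = femoralLrOverApRatioThreshold,
    sliceExtentPercentile = sliceExtentPercentile,
    sliceExtentCombine = match.arg(sliceExtentCombine),
    minCohortRows = as.integer(minCohortRows),
    percentileMethod = "linear interpolation between closest ranks (type 7)"),
    class = "modelConfig")
}

.featureRow <- function(mask) {
  n <- voxelCount(mask)
  if (n == 0L)
    return(data.frame(voxel_count = 0L, volume_mm3 = 0,
                      lr_range_mm = NA_real_, ap_range_mm = NA_real_,
                      is_range_mm = NA_real_, lr_over_ap = NA_real_,
                      lr_over_is = NA_real_, ap_over_is = NA_real_,
                      lr_rr_mm = NA_real_, ap_rr_mm = NA_real_,
                      empty_mask = TRUE))
  ext <- computeExtent(mask)
  ratios <- extentRatios(ext)
  se <- sliceExtents(mask)
  data.frame(voxel_count = n, volume_mm3 = computeVolume(mask),
             lr_range_mm = ext["lr", "range_mm"],
             ap_range_mm = ext["ap", "range_mm"],
             is_range_mm = ext["is", "range_mm"],
             lr_over_ap = unname(ratios["lr_over_ap"]),
             lr_over_is = unname(ratios["lr_over_is"]),
             ap_over_is = unname(ratios["ap_over_is"]),
             lr_rr_mm = se$lr_range_of_ranges_mm,
             ap_rr_mm = se$ap_range_of_ranges_mm,
             empty_mask = FALSE)
}

#' Build a cohort feature table
#'
#' One row per contour with the features the percentile models consume:
#' voxel count, volume (mm^3), per-axis extents (mm), the three extent
#' ratios (NA when undefined), and the LR/AP slice-extent ranges-of-ranges
#' (mm). Empty masks produce a row with \code{empty_mask = TRUE} and NA
#' shape features.
#'
#' @param masks a list of [StructureMask-class] objects, or a manifest
#'   data.frame from [readManifest()] (masks are loaded from
#'   \code{mask_path}).
#' @param patientIds,roiNames optional identifier columns (recycled from the
#'   manifest or mask \code{roiName} when omitted).
#' @return a data.frame (one row per contour) with identifier and feature
#'   columns.
#' @export
cohortFeatures <- function(masks, patientIds = NULL, roiNames = NULL) {
  if (is.data.frame(masks)) {
    manifest <- masks
    masks <- lapply(seq_len(nrow(manifest)), function(i)
      readMask(manifest$mask_path[i], roiName = manifest$roi_name[i]))
    if (is.null(patientIds)) patientIds <- manifest$patient_id
    if (is.null(roiNames)) roiNames <- manifest$roi_name
  }
  if (is.null(patientIds))
    patientIds <- sprintf("case%04d", seq_along(masks))
  if (is.null(roiNames))
    roiNames <- vapply(masks, roiName, character(1))
  rows <- do.call(rbind, lapply(masks, .featureRow))
  cbind(data.frame(patient_id = as.character(patientIds),
                   roi_name = as.character(roiNames)), rows)
}

.checkCohortSize <- function(cohort, config) {
  if (nrow(cohort) < config$minCohortRows)
    .cohortSizeError(nrow(cohort), config$minCohortRows)
}

#' Bladder emptiness model
#'
#' Flags contours suspected of representing an empty (or poorly contoured)
#' bladder: the row's volume must fall in the bottom cohort quartile (the
#' initial condition), and additionally at least one of the three extent
#' ratios must be extreme — below the cohort 10th or above the 90th
#' percentile. Rows with undefined ratios (degenerate geometry) automatically
#' satisfy the ratio condition. Ratio percentiles are computed over the full
#' cohort.
#'
#' @param cohort a feature table from [cohortFeatures()].
#' @param config a [modelConfig()].
#' @return a data.frame with \code{patient_id}, \code{roi_name},
#'   \code{flagged}, \code{volume_below_q}, \code{ratio_extreme} and the
#'   triggering feature values; the cohort thresholds applied are attached
#'   as the \code{"thresholds"} attribute.
#' @export
bladderModel <- function(cohort, config = modelConfig()) {
  .checkCohortSize(cohort, config)
  vThr <- cohortPercentile(cohort$volume_mm3, config$bladderVolumePercentile)
  ratioCols <- c("lr_over_ap", "lr_over_is", "ap_over_is")
  lims <- lapply(ratioCols, function(col) {
    v <- cohort[[col]][!is.na(cohort[[col]])]
    if (!length(v)) return(c(lo = NA_real_, hi = NA_real_))
    c(lo = cohortPercentile(v, config$bladderRatioLowPercentile),
      hi = cohortPercentile(v, config$bladderRatioHighPercentile))
  })
  names(lims) <- ratioCols
  ratioExtreme <- rep(FALSE, nrow(cohort))
  for (col in ratioCols) {
    v <- cohort[[col]]
    ratioExtreme <- ratioExtreme | is.na(v) |
      v < lims[[col]]["lo"] | v > lims[[col]]["hi"]
  }
  volBelow <- cohort$volume_mm3 < vThr
  out <- data.frame(patient_id = cohort$patient_id,
                    roi_name = cohort$roi_name,
                    volume_mm3 = cohort$volume_mm3,
                    volume_below_q = volBelow,
                    ratio_extreme = ratioExtreme,
                    flagged = volBelow & ratioExtreme)
  attr(out, "thresholds") <- c(list(volume_mm3 = vThr), lims)
  out
}

#' Femoral head ball/shaft distinction model
#'
#' Classifies each femoral-head contour as \code{ball_shaft} (the shaft was
#' contoured along with the ball) or \code{ball_only}. A row is
#' \code{ball_shaft} iff its volume exceeds the cohort volume percentile
#' gate AND its inferior-superior extent exceeds the configured mm threshold
#' AND its lateral/AP extent ratio is below the configured ratio threshold
#' (a shaft pulls the in-plane ratio toward 1, while a head+neck contour is
#' laterally elongated). A composite contour capturing only a small part of
#' the head fails the volume gate and falls back to \code{ball_only}.
#'
#' @inheritParams bladderModel
#' @return a data.frame with a \code{classification} column and the gate
#'   outcomes; thresholds attached as the \code{"thresholds"} attribute.
#' @export
femoralHeadModel <- function(cohort, config = modelConfig()) {
  .checkCohortSize(cohort, config)
  vThr <- cohortPercentile(cohort$volume_mm3, config$femoralVolumePercentile)
  volAbove <- cohort$volume_mm3 > vThr
  isLong <- !is.na(cohort$is_range_mm) &
    cohort$is_range_mm > config$femoralIsRangeMmThreshold
  symmetric <- !is.na(cohort$lr_over_ap) &
    cohort$lr_over_ap < config$femoralLrOverApRatioThreshold
  shaft <- volAbove & isLong & symmetric
  out <- data.frame(patient_id = cohort$patient_id,
                    roi_name = cohort$roi_name,
                    volume_mm3 = cohort$volume_mm3,
                    volume_above_gate = volAbove,
                    is_range_long = isLong,
                    lr_over_ap_symmetric = symmetric,
                    classification = ifelse(shaft, "ball_shaft", "ball_only"))
  attr(out, "thresholds") <- list(
    volume_mm3 = vThr,
    is_range_mm = config$femoralIsRangeMmThreshold,
    lr_over_ap = config$femoralLrOverApRatioThreshold)
  out
}

#' Slice-based extent outlier model
#'
#' Flags contours whose per-slice extent varies abnormally along the
#' inferior-superior axis: the LR and AP slice-extent ranges-of-ranges are
#' each compared with their cohort 90th percentile, and the two exceedances
#' are combined with AND (default) or OR.
#'
#' @inheritParams bladderModel
#' @return a data.frame with \code{flagged}, per-direction exceedances and
#'   feature values; thresholds attached as the \code{"thresholds"}
#'   attribute.
#' @export
sliceExtentModel <- function(cohort, config = modelConfig()) {
  .checkCohortSize(cohort, config)
  lrVals <- cohort$lr_rr_mm; apVals <- cohort$ap_rr_mm
  if (anyNA(lrVals) || anyNA(apVals))
    .validationError("slice-extent model requires non-empty masks (NA range-of-ranges present)")
  lrThr <- cohortPercentile(lrVals, config$sliceExtentPercentile)
  apThr <- cohortPercentile(apVals, config$sliceExtentPercentile)
  lrOut <- lrVals > lrThr
  apOut <- apVals > apThr
  flagged <- if (config$sliceExtentCombine == "and") lrOut & apOut
             else lrOut | apOut
  out <- data.frame(patient_id = cohort$patient_id,
                    roi_name = cohort$roi_name,
                    lr_rr_mm = lrVals, ap_rr_mm = apVals,
                    lr_exceeds = lrOut, ap_exceeds = apOut,
                    flagged = flagged)
  attr(out, "thresholds") <- list(lr_rr_mm = lrThr, ap_rr_mm = apThr,
                                  combine = config$sliceExtentCombine)
  out
}
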