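# ---- end-to-end QA run, report generation, rendering --------------------

.ALL_CHECKS <- c("extent", "region_growing", "bladder", "femoral",
                 "slice_extent")

#' Assemble a QA run configuration
#'
#' @param manifest path to a cohort manifest CSV, or a manifest data.frame.
#' @param checks subset of \code{c("extent", "region_growing", "bladder",
#'   "femoral", "slice_extent")}; at least one.
#' @param roiFilter optional character vector: only rows whose
#'   \code{roi_name} matches are analysed.
#' @param model a [modelConfig()].
#' @param contiguity a [contiguityConfig()].
#' @param outJson optional path for the JSON report.
#' @param stableOutput when TRUE (default) no timestamps are written, so
#'   identical inputs give byte-identical reports.
#' @return a list of class \code{runConfig}.
#' @export
runConfig <- function(manifest, checks = c("extent", "region_growing"),
                      roiFilter = NULL, model = modelConfig(),
                      contiguity = contiguityConfig(), outJson = NULL,
                      stableOutput = TRUE) {
  checks <- match.arg(checks, .ALL_CHECKS, several.ok = TRUE)
  if (!length(checks)) .validationError("at least one check must be selected")
  structure(list(manifest = manifest, checks = checks, roiFilter = roiFilter,
                 model = model, contiguity = contiguity, outJson = outJson,
                 stableOutput = isTRUE(stableOutput)),
            class = "runConfig")
}

#' Read a QA run configuration from YAML
#'
#' The YAML mirrors the [runConfig()] arguments: top-level \code{manifest},
#' \code{checks}, \code{roi_filter}, \code{out_json}, and nested
#' \code{model} / \code{contiguity} blocks whose keys are the respective
#' constructor arguments. The configuration round-trips losslessly through
#' [writeRunConfig()].
#'
#' @param path YAML file path.
#' @return a \code{runConfig} list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .ioError("config '%s' does not exist", path)
  y <- yaml::read_yaml(path)
  keepArgs <- function(x, fn) {
    x <- as.list(x %||% list())
    x[intersect(names(x), names(formals(fn)))]
  }
  model <- do.call(modelConfig, keepArgs(y$model, modelConfig))
  contiguity <- do.call(contiguityConfig, keepArgs(y$contiguity, contiguityConfig))
  runConfig(manifest = y$manifest,
            checks = unlist(y$checks) %||% c("extent", "region_growing"),
            roiFilter = unlist(y$roi_filter),
            model = model, contiguity = contiguity,
            outJson = y$out_json,
            stableOutput = y$stable_output %||% TRUE)
}

#' @rdname readRunConfig
#' @param config a \code{runConfig} whose \code{manifest} is a path.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  y <- list(manifest = config$manifest,
            checks = as.list(config$checks),
            roi_filter = as.list(config$roiFilter),
            model = unclass(config$model),
            contiguity = unclass(config$contiguity),
            out_json = config$outJson,
            stable_output = config$stableOutput)
  yaml::write_yaml(y, path, precision = 17L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# which cohort model applies to a roi_name group
.modelForRoi <- function(roi) {
  if (roi == "bladder") "bladder"
  else if (roi %in% c("femoral_head_left", "femoral_head_right")) "femoral"
  else "slice_extent"
}

#' Run the configured integrity checks over a cohort
#'
#' Loads every mask in the manifest (per-row read failures become an
#' \code{unreadable} flag, not a fatal error), computes per-contour
#' contiguity verdicts and cohort features, applies the selected cohort
#' models per ROI group, and summarises. When ground-truth labels are
#' present, a per-detector confusion summary (sensitivity, specificity,
#' precision, false-negative rate) is computed against the detectors each
#' planted defect is expected to trigger.
#'
#' @param config a [runConfig()].
#' @return a list of class \code{qaReport}: \code{rows} (per-contour flags
#'   and verdicts), \code{thresholds}, \code{summary} (counts per flag
#'   kind), and \code{confusion} (NULL without ground truth). Written as
#'   JSON to \code{config$outJson} when set.
#' @export
runChecks <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  manifest <- config$manifest
  if (is.character(manifest)) manifest <- readManifest(manifest)
  if (!is.null(config$roiFilter))
    manifest <- manifest[manifest$roi_name %in% config$roiFilter, ,
                         drop = FALSE]
  if (nrow(manifest) == 0L)
    .ioError("no manifest rows to analyse (empty manifest or roi filter matched nothing)")

  n <- nrow(manifest)
  masks <- vector("list", n)
  unreadable <- logical(n)
  for (i in seq_len(n)) {
    masks[i] <- list(tryCatch(
      readMask(manifest$mask_path[i], roiName = manifest$roi_name[i]),
      error = function(e) NULL))
    unreadable[i] <- is.null(masks[[i]])
  }
  if (all(unreadable)) .ioError("none of the %d manifest masks could be read", n)

  readable <- which(!unreadable)
  rows <- data.frame(patient_id = manifest$patient_id,
                     roi_name = manifest$roi_name,
                     ground_truth_label = manifest$ground_truth_label,
                     unreadable = unreadable,
                     empty_mask = FALSE,
                     stringsAsFactors = FALSE)
  for (chk in c("extent", "region_growing"))
    if (chk %in% config$checks)
      rows[[paste0("noncontiguous_", chk)]] <- NA

  feats <- cohortFeatures(masks[readable],
                          patientIds = manifest$patient_id[readable],
                          roiNames = manifest$roi_name[readable])
  rows$empty_mask[readable] <- feats$empty_mask

  for (i in readable) {
    m <- masks[[i]]
    if (voxelCount(m) == 0L) next
    if ("extent" %in% config$checks)
      rows$noncontiguous_extent[i] <-
        !isContiguous(checkExtentContiguity(m))
    if ("region_growing" %in% config$checks)
      rows$noncontiguous_region_growing[i] <-
        !isContiguous(checkRegionGrowingContiguity(m, config$contiguity))
  }

  thresholds <- list()
  modelCols <- c(bladder = "bladder_suspicious",
                 femoral = "femoral_classification",
                 slice_extent = "slice_extent_outlier")
  for (mc in intersect(c("bladder", "femoral", "slice_extent"),
                       config$checks))
    rows[[modelCols[[mc]]]] <- if (mc == "femoral") NA_character_ else NA
  for (roi in unique(feats$roi_name)) {
    grp <- feats[feats$roi_name == roi & !feats$empty_mask, , drop = FALSE]
    mdl <- .modelForRoi(roi)
    if (!mdl %in% config$checks) next
    if (nrow(grp) < config$model$minCohortRows) next
    res <- switch(mdl,
                  bladder = bladderModel(grp, config$model),
                  femoral = femoralHeadModel(grp, config$model),
                  slice_extent = sliceExtentModel(grp, config$model))
    thresholds[[roi]] <- attr(res, "thresholds")
    idx <- match(paste(res$patient_id, res$roi_name, sep = "\r"),
                 paste(rows$patient_id, rows$roi_name, sep = "\r"))
    if (mdl == "femoral") rows$femoral_classification[idx] <- res$classification
    else rows[[modelCols[[mdl]]]][idx] <- res$flagged
  }

  flagKinds <- c("unreadable", "empty_mask", "noncontiguous_extent",
                 "noncontiguous_region_growing", "bladder_suspicious",
                 "slice_extent_outlier")
  summary <- lapply(intersect(flagKinds, names(rows)), function(k)
    sum(rows[[k]] %in% TRUE))
  names(summary) <- intersect(flagKinds, names(rows))
  if ("femoral_classification" %in% names(rows))
    summary$femoral_ball_shaft <-
      sum(rows$femoral_classification %in% "ball_shaft")

  confusion <- NULL
  if (any(nzchar(rows$ground_truth_label))) {
    expected <- expectedDetectors(rows$ground_truth_label)
    detectorCols <- c(extent = "noncontiguous_extent",
                      region_growing = "noncontiguous_region_growing",
                      slice_extent = "slice_extent_outlier",
                      bladder = "bladder_suspicious")
    confusion <- list()
    for (det in names(detectorCols)) {
      col <- detectorCols[[det]]
      if (!col %in% names(rows)) next
      flagged <- rows[[col]] %in% TRUE
      exp <- vapply(expected, function(e) det %in% e, logical(1))
      tp <- sum(flagged & exp); fn <- sum(!flagged & exp)
      fp <- sum(flagged & !exp); tn <- sum(!flagged & !exp)
      confusion[[det]] <- list(
        tp = tp, fp = fp, fn = fn, tn = tn,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA,
        precision = if (tp + fp > 0) tp / (tp + fp) else NA,
        false_negative_rate = if (tp + fn > 0) fn / (tp + fn) else NA)
    }
  }

  report <- structure(list(rows = rows, thresholds = thresholds,
                           summary = summary, confusion = confusion,
                           checks = config$checks),
                      class = "qaReport")
  if (!config$stableOutput)
    report$generated_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(config$outJson))
    jsonlite::write_json(unclass(report), config$outJson, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  report
}

#' Render a three-view projection image of a mask
#'
#' Writes a grayscale PNG with axial (LR x AP), coronal (LR x IS) and
#' sagittal (AP x IS) maximum-intensity projections side by side. Each
#' panel's pixel dimensions equal the grid's physical extent in mm
#' (voxel indices multiplied by the voxel spacing, nearest-neighbour
#' resampled), so anisotropic spacing is rendered to scale.
#'
#' @param mask a non-empty [StructureMask-class].
#' @param out output PNG path.
#' @return \code{out}, invisibly.
#' @export
renderContour <- function(mask, out) {
  if (voxelCount(mask) == 0L) .emptyMaskError("renderContour")
  a <- maskArray(mask)
  sp <- mask@grid@spacing
  mips <- list(axial = apply(a, c(1L, 2L), max),
               coronal = apply(a, c(1L, 3L), max),
               sagittal = apply(a, c(2L, 3L), max))
  spacings <- list(axial = sp[c(1L, 2L)], coronal = sp[c(1L, 3L)],
                   sagittal = sp[c(2L, 3L)])
  resample <- function(m, s) {
    outDim <- pmax(1L, round(dim(m) * s))
    src1 <- pmin(dim(m)[1L], floor((seq_len(outDim[1L]) - 0.5) / s[1L]) + 1L)
    src2 <- pmin(dim(m)[2L], floor((seq_len(outDim[2L]) - 0.5) / s[2L]) + 1L)
    m[src1, src2, drop = FALSE]
  }
  panels <- Map(resample, mips, spacings)
  h <- max(vapply(panels, ncol, integer(1)))
  gap <- 2L
  canvas <- NULL
  for (p in panels) {
    pm <- matrix(0, nrow(p), h)
    pm[, seq_len(ncol(p))] <- p
    canvas <- if (is.null(canvas)) pm
              else rbind(canvas, matrix(0, gap, h), pm)
  }
  # png rows run top-down; flip the vertical axis so superior/anterior is up
  img <- t(canvas)[rev(seq_len(h)), , drop = FALSE]
  png::writePNG(img, out)
  invisible(out)
}
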