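# ---- mask and manifest I/O ----------------------------------------------

.MANIFEST_COLS <- c("patient_id", "roi_name", "mask_path", "ground_truth_label")
.KNOWN_ROIS <- c("bladder", "femoral_head_left", "femoral_head_right",
                 "rectum", "spinal_cord", "prostate", "brainstem")

.detectFormat <- function(path) {
  if (grepl("\\.rle\\.json$", path, ignore.case = TRUE)) "rle_json"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else .formatError("cannot infer mask format from extension of '%s'", path)
}

#' Read a structure mask
#'
#' Reads a binary mask from NIfTI (\code{.nii}/\code{.nii.gz}) or from the
#' package's RLE-JSON dialect (\code{.rle.json}). NIfTI volumes are
#' canonicalized to RAS axis order (x = left-right, y = anterior-posterior,
#' z = inferior-superior) before use, so the voxel set is independent of the
#' on-disk axis order; orientation metadata beyond axis order is ignored.
#' Voxel values are thresholded at 0.5.
#'
#' The RLE-JSON dialect is a JSON object
#' \code{{"dims": [X, Y, Z], "spacing_mm": [sx, sy, sz],
#' "transitions": [t1, t2, ...]}} with 0-based transitions into the
#' x-fastest linearization, strictly increasing, read as half-open runs.
#'
#' @param path path to the mask file.
#' @param format \code{"nifti"}, \code{"rle_json"}, or \code{"auto"}
#'   (from the extension).
#' @param roiName optional ROI label to attach.
#' @return a [StructureMask-class].
#' @export
readMask <- function(path, format = c("auto", "nifti", "rle_json"),
                     roiName = "") {
  format <- match.arg(format)
  if (!file.exists(path)) .ioError("mask file '%s' does not exist", path)
  if (format == "auto") format <- .detectFormat(path)
  if (format == "rle_json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      .formatError("cannot parse RLE-JSON '%s': %s",
                                   path, conditionMessage(e)))
    for (f in c("dims", "spacing_mm"))
      if (length(obj[[f]]) != 3L)
        .validationError("RLE-JSON '%s': field '%s' must have length 3",
                         path, f)
    grid <- VoxelGrid(obj$dims, obj$spacing_mm)
    tr <- obj$transitions
    if (is.null(tr)) tr <- integer(0)
    if (length(tr) %% 2L != 0L)
      .validationError("RLE-JSON '%s': odd transition count (%d)",
                       path, length(tr))
    StructureMask(as.integer(tr), grid, roiName = roiName)
  } else {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      .formatError("cannot read NIfTI '%s': %s",
                                   path, conditionMessage(e)))
    img <- tryCatch({ RNifti::orientation(img) <- "RAS"; img },
                    error = function(e) img)
    a <- as.array(img)
    if (length(dim(a)) != 3L)
      .validationError("NIfTI '%s' is %dD; expected a 3D volume",
                       path, length(dim(a)))
    vals <- unique(as.vector(a))
    if (any(!is.finite(vals)))
      .validationError("NIfTI '%s' contains non-finite voxel values", path)
    if (any(abs(vals) > 1e-6 & abs(vals - 1) > 1e-6))
      .validationError("NIfTI '%s' is not a binary mask: voxel values other than 0/1 present", path)
    sp <- abs(RNifti::pixdim(img)[1:3])
    grid <- VoxelGrid(dim(a), sp)
    StructureMask(array(as.integer(a > 0.5), dim = dim(a)), grid,
                  roiName = roiName)
  }
}

#' Write a structure mask
#'
#' The written file round-trips: \code{readMask(writeMask(m))} reproduces
#' the dense voxel set exactly and the spacing to 1e-6 mm. NIfTI output is
#' uint8 with the spacing carried in both pixdim and an RAS affine.
#'
#' @param mask a [StructureMask-class].
#' @param path output path; parent directory must exist.
#' @param format \code{"nifti"}, \code{"rle_json"}, or \code{"auto"}.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path, format = c("auto", "nifti", "rle_json")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    .ioError("parent directory '%s' does not exist", dirname(path))
  if (format == "auto") format <- .detectFormat(path)
  if (format == "rle_json") {
    obj <- list(dims = mask@grid@dims,
                spacing_mm = mask@grid@spacing,
                transitions = mask@transitions)
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  } else {
    sp <- mask@grid@spacing
    img <- RNifti::asNifti(maskArray(mask),
                           reference = list(pixdim = c(-1, sp, 0, 0, 0, 0)),
                           datatype = "uint8")
    aff <- diag(c(sp, 1))
    img <- RNifti::`qform<-`(img, value = structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Read a cohort manifest
#'
#' A cohort manifest is a CSV with columns \code{patient_id},
#' \code{roi_name}, \code{mask_path} and \code{ground_truth_label}
#' (\code{"clean"}, \code{"defect:<kind>"}, or empty). Lines starting with
#' \code{#} are header comments (the generator records its parameters
#' there). Duplicate (patient, roi) keys are rejected.
#'
#' @param path manifest CSV path.
#' @param checkPaths when TRUE (default), relative mask paths are resolved
#'   against the manifest's directory and rows whose file is missing get
#'   \code{file_exists = FALSE} rather than an error.
#' @return a data.frame with the manifest columns plus \code{file_exists}.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  if (!file.exists(path)) .ioError("manifest '%s' does not exist", path)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(setdiff(.MANIFEST_COLS, "ground_truth_label"), names(df))
  if (length(missing))
    .schemaError("manifest '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", "))
  if (!"ground_truth_label" %in% names(df)) df$ground_truth_label <- ""
  key <- paste(df$patient_id, df$roi_name, sep = "\r")
  if (anyDuplicated(key))
    .schemaError("manifest '%s' has duplicated (patient_id, roi_name) keys: %s",
                 path, paste(unique(sub("\r", "/", key[duplicated(key)])),
                             collapse = ", "))
  bad <- !(df$ground_truth_label %in% c("", "clean") |
           grepl("^defect:", df$ground_truth_label))
  if (any(bad))
    .schemaError("manifest '%s' has invalid ground_truth_label value(s): %s",
                 path, paste(unique(df$ground_truth_label[bad]), collapse = ", "))
  if (checkPaths) {
    resolved <- as.character(ifelse(grepl("^(/|[A-Za-z]:)", df$mask_path),
                                    df$mask_path,
                                    file.path(dirname(path), df$mask_path)))
    df$mask_path <- resolved
    df$file_exists <- file.exists(resolved)
  } else {
    df$file_exists <- NA
  }
  df
}

#' Write a cohort manifest
#'
#' @param manifest data.frame with the manifest columns.
#' @param path output CSV path.
#' @param headerLines optional character vector written as \code{# }-prefixed
#'   comment lines before the CSV header.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path, headerLines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(headerLines))
    writeLines(paste0("# ", headerLines), con)
  cols <- intersect(.MANIFEST_COLS, names(manifest))
  utils::write.csv(manifest[, cols, drop = FALSE], con, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
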