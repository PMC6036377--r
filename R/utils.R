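# classed conditions so callers can distinguish failure modes
.stopClassed <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "contourQA_error")))
}

.validationError <- function(fmt, ...) .stopClassed("contourQA_validation_error", fmt, ...)
.formatError     <- function(fmt, ...) .stopClassed("contourQA_format_error", fmt, ...)
.schemaError     <- function(fmt, ...) .stopClassed("contourQA_schema_error", fmt, ...)
.emptyMaskError  <- function(what) .stopClassed("contourQA_empty_mask_error",
                                                "%s is defined only for non-empty masks", what)
.cohortSizeError <- function(n, floor) .stopClassed("contourQA_cohort_size_error",
  "cohort has %d rows; percentile models require at least %d", n, floor)
.geometryError   <- function(fmt, ...) .stopClassed("contourQA_geometry_error", fmt, ...)
.ioError         <- function(fmt, ...) .stopClassed("contourQA_io_error", fmt, ...)

# derive a per-item seed from a master seed, kept inside 32-bit integer range
.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483629)
}
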