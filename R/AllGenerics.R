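#' @include AllClasses.R
NULL

#' Accessors for Spectrum objects
#'
#' @param object,x a \code{Spectrum}.
#' @return \code{wavelengths} and \code{spectrumValues} return numeric
#'   vectors; \code{unitsTag} returns the units string.
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setGeneric("spectrumValues",
           function(object) standardGeneric("spectrumValues"))

#' @rdname wavelengths
#' @export
setGeneric("unitsTag", function(object) standardGeneric("unitsTag"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(object) object@wavelengths)

#' @rdname wavelengths
#' @export
setMethod("spectrumValues", "Spectrum", function(object) object@values)

#' @rdname wavelengths
#' @export
setMethod("unitsTag", "Spectrum", function(object) object@units)

#' @export
#' @describeIn wavelengths number of samples in the spectrum.
setMethod("length", "Spectrum", function(x) length(x@wavelengths))

setMethod("show", "Spectrum", function(object) {
  n <- length(object@wavelengths)
  cat(sprintf("Spectrum: %d samples", n))
  if (n) {
    cat(sprintf(", %g-%g nm", min(object@wavelengths),
                max(object@wavelengths)))
  }
  cat(sprintf(" [%s]\n", object@units))
  if (n) {
    cat(sprintf("  total (rectangle rule): %.6g\n",
                sum(object@values) * gridStep(object@wavelengths)))
  }
  if (isTRUE(object@metadata$saturated)) cat("  ! saturated reading\n")
  invisible(object)
})

#' Accessor for DeviceSettings intensities
#'
#' @param object a \code{DeviceSettings}.
#' @return integer vector of 10 channel intensities.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "DeviceSettings", function(object) {
  object@intensities
})

setMethod("show", "DeviceSettings", function(object) {
  cat("DeviceSettings:", paste(object@intensities, collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "VideoFile", function(object) {
  cat(sprintf("VideoFile: %d frames, %d-%d ms\n", length(object@timesMs),
              min(object@timesMs), max(object@timesMs)))
  invisible(object)
})

setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf(
    "CalibrationTable: %d spectra (%d LEDs, %d levels/LED max), %d-%g nm\n",
    length(object@led), length(unique(object@led)),
    max(table(object@led)), min(object@wavelengths),
    max(object@wavelengths)))
  invisible(object)
})

setMethod("show", "CalibrationContext", function(object) {
  cat("CalibrationContext: 10 LEDs, dense 0-4095 lookup\n")
  cat(sprintf("  knots per LED: %s\n",
              paste(vapply(object@knotIntensities, length, integer(1)),
                    collapse = " ")))
  cat(sprintf("  max illuminance (all channels full): %.4g lx\n",
              sum(object@lux[4096L, ])))
  invisible(object)
})

setMethod("show", "TrialSegment", function(object) {
  cat(sprintf("TrialSegment: %d samples, %.2f to %.2f s re onset [%s]\n",
              length(object@time), min(object@time), max(object@time),
              object@units))
  invisible(object)
})

setMethod("show", "PLRParameters", function(object) {
  df <- as.data.frame(object)
  cat("PLR parameters:\n")
  print(df, row.names = FALSE, digits = 4)
  if (object@degenerate) cat("  (degenerate trial: no constriction)\n")
  invisible(object)
})

#' Coerce PLRParameters to a one-row data.frame
#'
#' Columns mirror the pupillometer-style parameter names: Baseline,
#' PeakCon, Latency, VConAve, VConMax, VRedAve, T75Rec.
#'
#' @param x a \code{PLRParameters} object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return one-row \code{data.frame}.
#' @export
as.data.frame.PLRParameters <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    Baseline = x@baseline, PeakCon = x@peakCon, Latency = x@latency,
    VConAve = x@vconAve, VConMax = x@vconMax, VRedAve = x@vredAve,
    T75Rec = x@t75Rec
  )
}

setMethod("show", "EngineGroundTruth", function(object) {
  peaks <- vapply(object@primaries, function(p) {
    if (length(p@values)) p@wavelengths[which.max(p@values)] else NA_real_
  }, numeric(1))
  cat("EngineGroundTruth: 10 primaries, peaks (nm):",
      paste(round(peaks), collapse = " "), "\n")
  cat(sprintf("  noise sd: %g\n", object@noiseSd))
  invisible(object)
})
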