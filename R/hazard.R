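#' @include photometry.R
NULL

#' Pupil correction factor for photobiological exposure limits
#'
#' Retinal exposure limits are derived for a reference pupil diameter
#' (3 mm). When the actual pupil is larger -- e.g. in a dark-adapted
#' observer -- retinal irradiance scales with pupil area, so the limit is
#' divided by the area ratio \code{(actual/reference)^2}. A fully dilated
#' 7 mm pupil against the 3 mm reference gives (7/3)^2 = 5.4 (often
#' rounded up to a factor of 6 in practice).
#'
#' @param actual_mm actual pupil diameter in mm (> 0).
#' @param reference_mm reference pupil diameter in mm (default 3).
#' @return dimensionless area ratio.
#' @examples
#' pupilCorrectionFactor(7)  # 5.44
#' @export
pupilCorrectionFactor <- function(actual_mm, reference_mm = 3) {
  if (actual_mm <= 0 || reference_mm <= 0) {
    stop("pupil diameters must be positive")
  }
  (actual_mm / reference_mm)^2
}

#' Blue-light-hazard weighted radiance and exposure-limit check
#'
#' Computes the blue-light weighted radiance
#' \code{L_B = sum(L_lambda * B(lambda) * delta_lambda)} over the
#' 300-700 nm support of B(lambda) and compares it against the
#' photobiological exposure limit: for exposures t <= 10^4 s the dose
#' \code{L_B * t} must not exceed 10^6 J m-2 sr-1; for t > 10^4 s the
#' radiance \code{L_B} must not exceed 100 W m-2 sr-1. Both limits are
#' divided by the pupil correction factor. The applied limit is reported
#' in radiance units (for short exposures, 10^6 / t / factor), so
#' \code{withinLimit} is always \code{lB <= exposureLimit}.
#'
#' @param spectrum a \code{Spectrum} tagged as radiance.
#' @param exposure_s exposure duration in seconds (> 0).
#' @param pupil_correction_factor dimensionless factor >= 1.
#' @return object of class \code{HazardResult}: list with \code{lB},
#'   \code{baseLimit}, \code{exposureLimit} (both W m-2 sr-1),
#'   \code{pupilCorrectionFactor}, \code{exposureS}, \code{dose} and
#'   \code{doseLimit} (J m-2 sr-1, short exposures only) and
#'   \code{withinLimit}.
#' @export
blueLightHazard <- function(spectrum, exposure_s,
                            pupil_correction_factor = 1) {
  if (unitsTag(spectrum) != "radiance") {
    stop("blue-light hazard requires a radiance-tagged spectrum")
  }
  if (exposure_s <= 0) stop("exposure_s must be positive")
  if (pupil_correction_factor < 1) {
    stop("pupil_correction_factor must be >= 1")
  }
  lB <- weightedIntegral(spectrum, weightingFunction("blue-light-hazard"))
  if (exposure_s <= 1e4) {
    baseLimit <- 1e6 / exposure_s
    dose <- lB * exposure_s
    doseLimit <- 1e6 / pupil_correction_factor
  } else {
    baseLimit <- 100
    dose <- NA_real_
    doseLimit <- NA_real_
  }
  exposureLimit <- baseLimit / pupil_correction_factor
  structure(list(
    lB = lB,
    baseLimit = baseLimit,
    exposureLimit = exposureLimit,
    pupilCorrectionFactor = pupil_correction_factor,
    exposureS = exposure_s,
    dose = dose,
    doseLimit = doseLimit,
    withinLimit = lB <= exposureLimit
  ), class = "HazardResult")
}

#' @export
print.HazardResult <- function(x, ...) {
  cat("Blue-light-hazard assessment\n")
  cat(sprintf("  L_B: %.6g W m-2 sr-1\n", x$lB))
  cat(sprintf("  exposure: %g s, pupil correction factor: %g\n",
              x$exposureS, x$pupilCorrectionFactor))
  cat(sprintf("  applied limit: %s W m-2 sr-1\n",
              truncate1dp(x$exposureLimit)))
  cat(sprintf("  within limit: %s\n", x$withinLimit))
  invisible(x)
}

# report convention: limits printed truncated to one decimal place
truncate1dp <- function(x) sprintf("%.1f", floor(x * 10) / 10)

#' Serialise a hazard assessment to JSON
#'
#' @param x a \code{HazardResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeHazardJson <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
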