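#' @include weighting.R
NULL

#' Rectangle-rule weighted integral of a spectrum
#'
#' Computes \code{sum(values * weights) * delta_lambda} over the
#' intersection of the spectrum's and the weighting function's supports,
#' with the weights linearly interpolated onto the spectrum's grid and
#' \code{delta_lambda} equal to the grid step. Note the rectangle-rule
#' convention: the sample count, not the interval count, sets the value
#' for a constant spectrum (a unit spectrum times a unit weight over
#' 400-500 nm at 1 nm gives 101, not 100).
#'
#' @param spectrum a \code{Spectrum}.
#' @param w a \code{WeightingFunction}.
#' @return scalar integral; 0 with a warning when the supports are
#'   disjoint.
#' @export
weightedIntegral <- function(spectrum, w) {
  stopifnot(is(spectrum, "Spectrum"), inherits(w, "WeightingFunction"))
  wl <- spectrum@wavelengths
  keep <- wl >= min(w$wavelengths) & wl <= max(w$wavelengths)
  if (!any(keep)) {
    warning("spectrum and weighting function have disjoint supports")
    return(0)
  }
  wlk <- wl[keep]
  wk <- stats::approx(w$wavelengths, w$weights, xout = wlk, rule = 1)$y
  sum(spectrum@values[keep] * wk) * gridStep(wlk)
}

#' Alpha-opic irradiances of a spectrum
#'
#' Weighted integrals of an irradiance spectrum against the five
#' photoreceptor action spectra (S-, M-, L-cone-opic, rhodopic,
#' melanopic), in canonical order.
#'
#' @param spectrum a \code{Spectrum} tagged as irradiance.
#' @return named numeric vector of 5 alpha-opic irradiances (W m-2,
#'   effective).
#' @export
aopicIrradiance <- function(spectrum) {
  if (unitsTag(spectrum) != "irradiance") {
    stop("alpha-opic irradiance requires an irradiance-tagged spectrum")
  }
  out <- vapply(aopicNames(),
                function(nm) weightedIntegral(spectrum,
                                              weightingFunction(nm)),
                numeric(1))
  names(out) <- aopicNames()
  out
}

#' Photopic illuminance of a spectrum
#'
#' 683 lm/W times the weighted integral against V(lambda).
#'
#' @param spectrum a \code{Spectrum} tagged as irradiance.
#' @return illuminance in lux.
#' @export
photopicIlluminance <- function(spectrum) {
  if (unitsTag(spectrum) != "irradiance") {
    stop("illuminance requires an irradiance-tagged spectrum")
  }
  683 * weightedIntegral(spectrum, weightingFunction("photopic"))
}

#' CIE 1931 chromaticity coordinates of a spectrum
#'
#' @param spectrum a non-zero \code{Spectrum}.
#' @return named numeric c(x, y).
#' @export
chromaticityXY <- function(spectrum) {
  X <- weightedIntegral(spectrum, weightingFunction("cie-x"))
  Y <- weightedIntegral(spectrum, weightingFunction("cie-y"))
  Z <- weightedIntegral(spectrum, weightingFunction("cie-z"))
  s <- X + Y + Z
  if (s <= 0) stop("chromaticity undefined for a zero spectrum")
  c(x = X / s, y = Y / s)
}

#' Total (unweighted) integrated irradiance
#'
#' @param spectrum a \code{Spectrum}.
#' @return rectangle-rule integral of the values (e.g. W m-2).
#' @export
totalIrradiance <- function(spectrum) {
  if (!length(spectrum@values)) return(0)
  sum(spectrum@values) * gridStep(spectrum@wavelengths)
}
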