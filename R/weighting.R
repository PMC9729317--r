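#' @include spectrum.R
NULL

# cache: weighting tables are deterministic, build once per session
.wfCache <- new.env(parent = emptyenv())

#' Spectral weighting functions
#'
#' Builds the spectral weighting functions used throughout the package:
#' the five alpha-opic photoreceptor action spectra (S-, M-, L-cone-opic,
#' rhodopic, melanopic), the photopic luminous efficiency function V(lambda),
#' the blue-light-hazard function B(lambda), and the CIE 1931 2-degree
#' colour matching functions.
#'
#' The tables are constructed analytically rather than read from file:
#' the alpha-opic action spectra from the Govardovskii A1 visual-pigment
#' template placed at the nominal corneal peak wavelengths (448, 542, 568,
#' 507 and 490 nm) and normalised to unit peak; the colour matching
#' functions (and V(lambda) = ybar) from the published piecewise-Gaussian
#' analytic fits; and B(lambda) from its standard piecewise definition
#' (tabulated 300-500 nm at 5 nm, 10^((450-lambda)/50) on 500-600 nm,
#' 0.001 on 600-700 nm). They are faithful analytic constructions of the
#' standard functions, not verbatim copies of the published tabulations.
#'
#' @param name one of \code{"S-cone-opic"}, \code{"M-cone-opic"},
#'   \code{"L-cone-opic"}, \code{"rhodopic"}, \code{"melanopic"},
#'   \code{"photopic"}, \code{"blue-light-hazard"}, \code{"cie-x"},
#'   \code{"cie-y"}, \code{"cie-z"}.
#' @return an object of class \code{WeightingFunction}: a list with
#'   \code{name}, \code{wavelengths} (nm, 1 nm step) and non-negative
#'   \code{weights}.
#' @examples
#' mel <- weightingFunction("melanopic")
#' mel$wavelengths[which.max(mel$weights)]  # peak near 490 nm
#' @export
weightingFunction <- function(name = c("S-cone-opic", "M-cone-opic",
                                       "L-cone-opic", "rhodopic",
                                       "melanopic", "photopic",
                                       "blue-light-hazard",
                                       "cie-x", "cie-y", "cie-z")) {
  name <- match.arg(name)
  if (!is.null(.wfCache[[name]])) return(.wfCache[[name]])
  wl <- if (name == "blue-light-hazard") seq(300, 700, 1) else defaultGrid()
  w <- switch(name,
    "S-cone-opic" = pigmentTemplate(wl, 448),
    "M-cone-opic" = pigmentTemplate(wl, 542),
    "L-cone-opic" = pigmentTemplate(wl, 568),
    "rhodopic" = pigmentTemplate(wl, 507),
    "melanopic" = pigmentTemplate(wl, 490),
    "photopic" = cmfFit(wl, "y"),
    "blue-light-hazard" = blueHazardWeights(wl),
    "cie-x" = cmfFit(wl, "x"),
    "cie-y" = cmfFit(wl, "y"),
    "cie-z" = cmfFit(wl, "z")
  )
  out <- structure(list(name = name, wavelengths = wl, weights = pmax(w, 0)),
                   class = "WeightingFunction")
  .wfCache[[name]] <- out
  out
}

#' @export
print.WeightingFunction <- function(x, ...) {
  cat(sprintf("WeightingFunction '%s': %g-%g nm, peak %.3g at %g nm\n",
              x$name, min(x$wavelengths), max(x$wavelengths),
              max(x$weights), x$wavelengths[which.max(x$weights)]))
  invisible(x)
}

#' Construct a synthetic narrowband weighting function
#'
#' A triangular band of unit peak, used by tests that must not depend on
#' the provenance of the standard tables.
#'
#' @param center peak wavelength (nm).
#' @param halfwidth half-width at base (nm).
#' @param wl wavelength grid.
#' @return a \code{WeightingFunction}.
#' @export
narrowbandWeighting <- function(center, halfwidth = 10, wl = defaultGrid()) {
  w <- pmax(0, 1 - abs(wl - center) / halfwidth)
  structure(list(name = sprintf("narrowband-%g", center),
                 wavelengths = wl, weights = w),
            class = "WeightingFunction")
}

# Govardovskii A1 visual-pigment template (alpha + beta band), peak 1
pigmentTemplate <- function(wl, lambdaMax) {
  x <- lambdaMax / wl
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alphaBand <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambdaMax
  bb <- -40.5 + 0.195 * lambdaMax
  betaBand <- 0.26 * exp(-((wl - lmb) / bb)^2)
  s <- alphaBand + betaBand
  s / max(s)
}

# piecewise-Gaussian analytic fits to the CIE 1931 2-degree CMFs
cmfFit <- function(wl, which) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  switch(which,
    x = 1.056 * g(wl, 599.8, 37.9, 31.0) +
        0.362 * g(wl, 442.0, 16.0, 26.7) -
        0.065 * g(wl, 501.1, 20.4, 26.2),
    y = 0.821 * g(wl, 568.8, 46.9, 40.5) +
        0.286 * g(wl, 530.9, 16.3, 31.1),
    z = 1.217 * g(wl, 437.0, 11.8, 36.0) +
        0.681 * g(wl, 459.0, 26.0, 13.8)
  )
}

# blue-light-hazard weighting: 5 nm table 300-500, log-linear 500-600 tail
blueHazardWeights <- function(wl) {
  tabWl <- seq(300, 500, 5)
  tabW <- c(rep(0.01, 17),               # 300-380
            0.013, 0.025, 0.05,          # 385-395
            0.10, 0.20, 0.40, 0.80,      # 400-415
            0.90, 0.95, 0.98, 1.00, 1.00, # 420-440
            0.97, 0.94, 0.90,            # 445-455
            0.80, 0.70, 0.62, 0.55,      # 460-475
            0.45, 0.40, 0.22, 0.16, 0.10) # 480-500
  stopifnot(length(tabW) == length(tabWl))
  w <- numeric(length(wl))
  lo <- wl <= 500
  w[lo] <- stats::approx(tabWl, tabW, xout = wl[lo], rule = 2)$y
  mid <- wl > 500 & wl <= 600
  w[mid] <- 10^((450 - wl[mid]) / 50)
  hi <- wl > 600
  w[hi] <- 0.001
  w
}

#' Names of the five alpha-opic channels, in canonical order
#' @return character vector of length 5.
#' @export
aopicNames <- function() {
  c("S-cone-opic", "M-cone-opic", "L-cone-opic", "rhodopic", "melanopic")
}
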