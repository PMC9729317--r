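#' @include AllClasses.R
NULL

# step of a (near-)uniform wavelength grid; errors if wildly non-uniform
gridStep <- function(wl) {
  if (length(wl) < 2L) return(1)
  d <- diff(wl)
  step <- stats::median(d)
  if (any(abs(d - step) > 0.01 * step)) {
    stop("wavelength grid must be uniform for rectangle-rule integration")
  }
  step
}

#' Construct a Spectrum
#'
#' @param wavelengths strictly increasing wavelength grid in nm.
#' @param values non-negative power values, one per wavelength.
#' @param units \code{"irradiance"} (W m-2 nm-1), \code{"radiance"}
#'   (W m-2 sr-1 nm-1) or \code{"counts"}.
#' @param metadata optional list of provenance fields.
#' @param clamp if TRUE, small negative values (e.g. from dark
#'   subtraction) are clamped to zero instead of failing validity.
#' @return a \code{Spectrum}.
#' @examples
#' s <- Spectrum(380:780, rep(1, 401))
#' photopicIlluminance(s)
#' @export
Spectrum <- function(wavelengths, values, units = "irradiance",
                     metadata = list(), clamp = FALSE) {
  if (clamp) values <- pmax(values, 0)
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), units = units, metadata = metadata)
}

#' The default 380-780 nm, 1 nm stimulus grid
#' @return numeric vector 380, 381, ..., 780.
#' @export
defaultGrid <- function() seq(380, 780, by = 1)

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto \code{grid}; wavelengths outside the source
#' support get zero power.
#'
#' @param spectrum a \code{Spectrum}.
#' @param grid strictly increasing target grid within [300, 800] nm.
#' @return a \code{Spectrum} on \code{grid}, same units.
#' @export
resampleSpectrum <- function(spectrum, grid) {
  grid <- as.numeric(grid)
  if (length(grid) < 1L || (length(grid) > 1L && any(diff(grid) <= 0))) {
    stop("target grid must be strictly increasing")
  }
  if (min(grid) < 300 || max(grid) > 800) {
    stop("target grid must lie within [300, 800] nm")
  }
  v <- interpZero(spectrum@wavelengths, spectrum@values, grid)
  Spectrum(grid, v, units = spectrum@units, metadata = spectrum@metadata)
}

# linear interpolation with zero fill outside the source support
interpZero <- function(x, y, xout) {
  if (length(x) == 0L) return(rep(0, length(xout)))
  if (length(x) == 1L) {
    return(ifelse(xout == x, y, 0))
  }
  out <- stats::approx(x, y, xout = xout, method = "linear",
                       yleft = 0, yright = 0)$y
  out
}

#' Arithmetic on spectra sharing a grid
#'
#' \code{addSpectra} sums spectra defined on identical grids;
#' \code{scaleSpectrum} multiplies by a non-negative scalar.
#'
#' @param ... \code{Spectrum} objects on the same grid and units.
#' @return a \code{Spectrum}.
#' @export
addSpectra <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !is(specs[[1L]], "Spectrum")) {
    specs <- specs[[1L]]
  }
  stopifnot(length(specs) >= 1L)
  wl <- specs[[1L]]@wavelengths
  v <- rep(0, length(wl))
  for (s in specs) {
    if (!isTRUE(all.equal(s@wavelengths, wl))) {
      stop("spectra must share a wavelength grid")
    }
    v <- v + s@values
  }
  Spectrum(wl, v, units = specs[[1L]]@units)
}

#' @rdname addSpectra
#' @param spectrum a \code{Spectrum}.
#' @param factor non-negative scalar.
#' @export
scaleSpectrum <- function(spectrum, factor) {
  stopifnot(factor >= 0)
  Spectrum(spectrum@wavelengths, spectrum@values * factor,
           units = spectrum@units, metadata = spectrum@metadata)
}

#' Read and write spectra as two-column CSV
#'
#' The on-disk format is a two-column CSV (\code{wavelength_nm, value})
#' with the units tag recorded in a leading comment line
#' (\code{# units: irradiance}).
#'
#' @param path file path.
#' @return \code{readSpectrumCsv} returns a \code{Spectrum}.
#' @export
readSpectrumCsv <- function(path) {
  first <- readLines(path, n = 1L)
  units <- "irradiance"
  if (grepl("^#\\s*units:", first)) {
    units <- trimws(sub("^#\\s*units:", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#")
  Spectrum(df[[1L]], df[[2L]], units = units)
}

#' @rdname readSpectrumCsv
#' @param spectrum a \code{Spectrum} to write.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", spectrum@units), con)
  utils::write.csv(
    data.frame(wavelength_nm = spectrum@wavelengths,
               value = spectrum@values),
    con, row.names = FALSE)
  invisible(path)
}
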