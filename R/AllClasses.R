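#' @import methods
NULL

#' Spectrum: wavelength-indexed spectral power values
#'
#' The currency of all photometric computation in the package. A
#' \code{Spectrum} holds power values on a strictly increasing wavelength
#' grid (by convention 380--780 nm at 1 nm for stimulus spectra) together
#' with a units tag saying what the values are: spectral irradiance
#' (W m-2 nm-1), spectral radiance (W m-2 sr-1 nm-1) or raw sensor counts.
#'
#' @slot wavelengths numeric, strictly increasing wavelength grid in nm.
#' @slot values numeric, non-negative power per nm, same length as the grid.
#' @slot units character, one of \code{"irradiance"}, \code{"radiance"},
#'   \code{"counts"}.
#' @slot metadata list of free-form provenance fields (e.g. integration
#'   time, saturation flag for simulated spectrometer readings).
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    wavelengths = "numeric",
    values = "numeric",
    units = "character",
    metadata = "list"
  ),
  prototype(
    wavelengths = numeric(0), values = numeric(0),
    units = "irradiance", metadata = list()
  )
)

setValidity("Spectrum", function(object) {
  msg <- character(0)
  wl <- object@wavelengths
  v <- object@values
  if (length(wl) != length(v)) {
    msg <- c(msg, "wavelengths and values must have equal length")
  }
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    msg <- c(msg, "wavelengths must be strictly increasing")
  }
  if (length(v) && any(!is.finite(v))) {
    msg <- c(msg, "values must be finite")
  } else if (length(v) && any(v < 0)) {
    msg <- c(msg, "values must be non-negative")
  }
  if (length(object@units) != 1L ||
      !object@units %in% c("irradiance", "radiance", "counts")) {
    msg <- c(msg, "units must be one of 'irradiance', 'radiance', 'counts'")
  }
  if (length(msg)) msg else TRUE
})

#' DeviceSettings: a ten-channel 12-bit light engine command
#'
#' Exactly ten integer intensities in [0, 4095], one per LED channel.
#'
#' @slot intensities integer vector of length 10.
#' @exportClass DeviceSettings
setClass("DeviceSettings", representation(intensities = "integer"))

setValidity("DeviceSettings", function(object) {
  s <- object@intensities
  if (length(s) != 10L) {
    return("settings must have exactly 10 channels")
  }
  if (any(is.na(s))) {
    return("settings must not contain NA")
  }
  if (any(s < 0L | s > 4095L)) {
    return("settings must be 12-bit integers in [0, 4095]")
  }
  TRUE
})

#' VideoFile: a timed spectral switching sequence
#'
#' Pairs a strictly increasing, non-negative time vector (ms) with one
#' \code{DeviceSettings} per time point. The engine switches spectra no
#' faster than once every 10 ms, enforced by validity.
#'
#' @slot timesMs integer vector, non-negative, strictly increasing,
#'   consecutive differences >= 10 ms.
#' @slot frames integer matrix, one row per time point, 10 columns.
#' @slot metadata list of free-form fields.
#' @exportClass VideoFile
setClass("VideoFile",
  representation(timesMs = "integer", frames = "matrix", metadata = "list"),
  prototype(metadata = list())
)

setValidity("VideoFile", function(object) {
  t <- object@timesMs
  f <- object@frames
  msg <- character(0)
  if (length(t) < 1L) msg <- c(msg, "at least one frame required")
  if (length(t) && t[1L] < 0L) msg <- c(msg, "times must be non-negative")
  if (length(t) > 1L && any(diff(t) < 10L)) {
    msg <- c(msg, "spectral switching interval below the 10 ms device floor")
  }
  if (length(t) > 1L && any(diff(t) <= 0L)) {
    msg <- c(msg, "times must be strictly increasing")
  }
  if (nrow(f) != length(t) || ncol(f) != 10L) {
    msg <- c(msg, "frames must be a length(times) x 10 matrix")
  }
  if (length(f) && (any(is.na(f)) || any(f < 0L | f > 4095L))) {
    msg <- c(msg, "frame settings must be in [0, 4095]")
  }
  if (length(msg)) msg else TRUE
})

#' EngineGroundTruth: forward model of a simulated ten-primary engine
#'
#' Describes the simulated rig: per-channel primary spectra at maximum
#' drive, a beta-CDF input nonlinearity per channel, a dark spectrum, and
#' measurement noise. Stands in for the physical engine so that the
#' calibration and matching machinery can be exercised against known truth.
#'
#' @slot primaries list of 10 \code{Spectrum} (per-LED output at maximum).
#' @slot alpha,beta numeric(10), beta-CDF shape parameters (> 0) mapping
#'   normalised drive s/4095 to relative output.
#' @slot dark \code{Spectrum}, output at zero drive.
#' @slot noiseSd numeric(1), Gaussian noise sd added per wavelength sample.
#' @exportClass EngineGroundTruth
setClass("EngineGroundTruth",
  representation(
    primaries = "list", alpha = "numeric", beta = "numeric",
    dark = "ANY", noiseSd = "numeric"
  )
)

setValidity("EngineGroundTruth", function(object) {
  msg <- character(0)
  if (length(object@primaries) != 10L) {
    msg <- c(msg, "exactly 10 primaries required")
  }
  if (!all(vapply(object@primaries, is, logical(1), "Spectrum"))) {
    msg <- c(msg, "primaries must be Spectrum objects")
  }
  if (length(object@alpha) != 10L || any(object@alpha <= 0)) {
    msg <- c(msg, "alpha must be 10 positive values")
  }
  if (length(object@beta) != 10L || any(object@beta <= 0)) {
    msg <- c(msg, "beta must be 10 positive values")
  }
  if (!is(object@dark, "Spectrum")) msg <- c(msg, "dark must be a Spectrum")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0) {
    msg <- c(msg, "noiseSd must be a single non-negative value")
  }
  if (length(msg)) msg else TRUE
})

#' CalibrationTable: raw per-channel spectral measurements
#'
#' One calibrated spectrum per (LED channel, 12-bit level) pair, all on a
#' common wavelength grid.
#'
#' @slot led integer vector of channel indices (0--9), one per record.
#' @slot intensity integer vector of 12-bit levels, one per record.
#' @slot wavelengths numeric, the common wavelength grid (nm).
#' @slot spectra numeric matrix, one row per record (irradiance units).
#' @exportClass CalibrationTable
setClass("CalibrationTable",
  representation(
    led = "integer", intensity = "integer",
    wavelengths = "numeric", spectra = "matrix"
  )
)

setValidity("CalibrationTable", function(object) {
  msg <- character(0)
  n <- length(object@led)
  if (length(object@intensity) != n || nrow(object@spectra) != n) {
    msg <- c(msg, "led, intensity and spectra rows must align")
  }
  if (ncol(object@spectra) != length(object@wavelengths)) {
    msg <- c(msg, "spectra columns must match the wavelength grid")
  }
  if (n && any(object@led < 0L | object@led > 9L)) {
    msg <- c(msg, "led indices must be 0-9")
  }
  if (n && any(object@intensity < 0L | object@intensity > 4095L)) {
    msg <- c(msg, "intensities must be in [0, 4095]")
  }
  if (n && anyDuplicated(paste(object@led, object@intensity))) {
    msg <- c(msg, "one spectrum per (led, intensity) pair")
  }
  if (length(msg)) msg else TRUE
})

#' CalibrationContext: the calibrated forward model of the engine
#'
#' Per-channel interpolation knots over intensity plus dense per-integer
#' lookup tables of derived scalars (photopic illuminance, the five
#' alpha-opic irradiances, and unweighted irradiance) for every 12-bit
#' level. Spectra at unmeasured levels are linearly interpolated between
#' knots; because all derived scalars are linear functionals of the
#' spectrum, interpolating the scalars is exactly equivalent.
#'
#' @slot wavelengths numeric, common wavelength grid (nm).
#' @slot knotIntensities list of 10 integer vectors (per-LED measured levels,
#'   zero-anchored).
#' @slot knotSpectra list of 10 matrices (levels x wavelengths).
#' @slot lux 4096 x 10 matrix of photopic illuminance per level and LED.
#' @slot irradiance 4096 x 10 matrix of unweighted integrated irradiance.
#' @slot aopic 4096 x 10 x 5 array of alpha-opic irradiances.
#' @exportClass CalibrationContext
setClass("CalibrationContext",
  representation(
    wavelengths = "numeric",
    knotIntensities = "list",
    knotSpectra = "list",
    lux = "matrix",
    irradiance = "matrix",
    aopic = "array"
  )
)

setValidity("CalibrationContext", function(object) {
  msg <- character(0)
  if (length(object@knotIntensities) != 10L ||
      length(object@knotSpectra) != 10L) {
    msg <- c(msg, "10 LED channels required")
  }
  if (!identical(dim(object@lux), c(4096L, 10L))) {
    msg <- c(msg, "lux lookup must be 4096 x 10")
  }
  if (!identical(dim(object@aopic), c(4096L, 10L, 5L))) {
    msg <- c(msg, "aopic lookup must be 4096 x 10 x 5")
  }
  for (i in seq_len(min(10L, length(object@knotIntensities)))) {
    k <- object@knotIntensities[[i]]
    if (length(k) < 2L) {
      msg <- c(msg, sprintf("LED %d has fewer than 2 calibration levels",
                            i - 1L))
    } else if (any(diff(k) <= 0)) {
      msg <- c(msg, sprintf("LED %d knot intensities must increase", i - 1L))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TrialSegment: one trial of pupil data re-indexed to stimulus onset
#'
#' @slot time numeric, time relative to onset in seconds (from -pre to +post).
#' @slot values numeric, pupil diameter (mm or px) or percent change.
#' @slot onset numeric(1), the absolute onset timestamp (s).
#' @slot units character, one of \code{"mm"}, \code{"px"},
#'   \code{"percent_change"}.
#' @exportClass TrialSegment
setClass("TrialSegment",
  representation(
    time = "numeric", values = "numeric",
    onset = "numeric", units = "character"
  )
)

setValidity("TrialSegment", function(object) {
  msg <- character(0)
  if (length(object@time) != length(object@values)) {
    msg <- c(msg, "time and values must align")
  }
  if (length(object@time) > 1L && any(diff(object@time) <= 0)) {
    msg <- c(msg, "time must be strictly increasing")
  }
  if (!object@units %in% c("mm", "px", "percent_change")) {
    msg <- c(msg, "units must be 'mm', 'px' or 'percent_change'")
  }
  if (length(msg)) msg else TRUE
})

#' PLRParameters: pupillometer-style summary of one PLR trial
#'
#' Parameters follow the conventions of clinical automated pupillometers:
#' baseline and peak-constriction diameters, constriction latency (time
#' from stimulus onset to the negative acceleration peak of the initial
#' constriction), average and maximum constriction velocity (signed
#' negative), average redilation velocity (positive), and the time taken
#' after peak constriction to recover 75% of the constriction amplitude
#' (\code{t75Rec}; NA when the trace never recovers that far in-window).
#'
#' @slot baseline,peakCon numeric(1), diameters in trace units.
#' @slot latency numeric(1), seconds from onset.
#' @slot vconAve,vconMax,vredAve numeric(1), velocities in units/s.
#' @slot t75Rec numeric(1), seconds from peak constriction (may be NA).
#' @slot accPeakTime numeric(1), diagnostic: time of acceleration minimum.
#' @slot degenerate logical(1), TRUE when no constriction was found.
#' @exportClass PLRParameters
setClass("PLRParameters",
  representation(
    baseline = "numeric", peakCon = "numeric", latency = "numeric",
    vconAve = "numeric", vconMax = "numeric", vredAve = "numeric",
    t75Rec = "numeric", accPeakTime = "numeric", degenerate = "logical"
  )
)
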