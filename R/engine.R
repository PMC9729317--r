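#' @include spectrum.R
NULL

#' Construct DeviceSettings
#'
#' @param intensities 10 integers in [0, 4095], one per LED channel.
#' @return a \code{DeviceSettings}.
#' @examples
#' deviceSettings(rep(2048, 10))
#' @export
deviceSettings <- function(intensities) {
  x <- as.numeric(intensities)
  if (any(is.na(x)) || any(x != round(x))) {
    stop("settings must be integral")
  }
  new("DeviceSettings", intensities = as.integer(round(x)))
}

#' All-zero and all-maximum settings
#' @return a \code{DeviceSettings}.
#' @export
darkSettings <- function() deviceSettings(rep(0L, 10L))

#' @rdname darkSettings
#' @export
maxSettings <- function() deviceSettings(rep(4095L, 10L))

#' Settings with a single channel driven
#' @param led channel index 0-9.
#' @param intensity 12-bit level.
#' @return a \code{DeviceSettings}.
#' @export
singleChannelSettings <- function(led, intensity) {
  s <- rep(0L, 10L)
  s[led + 1L] <- as.integer(intensity)
  deviceSettings(s)
}

#' Build a video file from a stimulus profile
#'
#' Converts a table of switching times and settings into a validated
#' \code{VideoFile}. Switching intervals below the 10 ms device floor are
#' a validation error, not silently coalesced.
#'
#' @param profile a \code{data.frame} with column \code{time_ms} and
#'   either ten columns \code{LED0}..\code{LED9} or a list column
#'   \code{settings} of \code{DeviceSettings}.
#' @param metadata optional list stored in the file header.
#' @return a \code{VideoFile}.
#' @export
makeVideoFile <- function(profile, metadata = list()) {
  stopifnot(is.data.frame(profile), "time_ms" %in% names(profile))
  t <- as.integer(profile$time_ms)
  if (anyDuplicated(t)) stop("switching times must be unique")
  o <- order(t)
  t <- t[o]
  if ("settings" %in% names(profile)) {
    mat <- do.call(rbind, lapply(profile$settings[o], function(s) {
      if (is(s, "DeviceSettings")) intensities(s) else
        intensities(deviceSettings(s))
    }))
  } else {
    ledCols <- paste0("LED", 0:9)
    if (!all(ledCols %in% names(profile))) {
      stop("profile needs LED0..LED9 columns or a settings column")
    }
    mat <- as.matrix(profile[o, ledCols])
    apply(mat, 1L, function(r) deviceSettings(r)) # validate rows
    storage.mode(mat) <- "integer"
  }
  dimnames(mat) <- NULL
  new("VideoFile", timesMs = t, frames = mat, metadata = metadata)
}

#' A timed pulse stimulus
#'
#' Convenience constructor: \code{settings} at t = 0, all channels off at
#' t = \code{duration_ms}.
#'
#' @param settings a \code{DeviceSettings}.
#' @param duration_ms pulse duration, >= 10 ms.
#' @return a two-frame \code{VideoFile}.
#' @examples
#' pulseVideo(maxSettings(), 1000)  # a one-second pulse
#' @export
pulseVideo <- function(settings, duration_ms) {
  if (duration_ms < 10) {
    stop("pulse duration below the 10 ms spectral switching floor")
  }
  new("VideoFile",
      timesMs = c(0L, as.integer(duration_ms)),
      frames = rbind(intensities(settings), rep(0L, 10L)),
      metadata = list(kind = "pulse"))
}

#' Read and write video files (.dsf JSON)
#'
#' The on-disk format is a documented JSON schema
#' \code{{metadata: {...}, frames: [{time_ms, settings: [10]}]}} written
#' with a ".dsf" extension. It is a stand-in with the same information
#' content as the vendor's dynamic sequence files, not a bit-compatible
#' clone of that proprietary format.
#'
#' @param video a \code{VideoFile}.
#' @param path output path (conventionally ending ".dsf").
#' @return \code{writeVideoFile} returns the path invisibly;
#'   \code{readVideoFile} returns a \code{VideoFile}.
#' @export
writeVideoFile <- function(video, path) {
  frames <- lapply(seq_along(video@timesMs), function(i) {
    list(time_ms = video@timesMs[i], settings = video@frames[i, ])
  })
  obj <- list(metadata = video@metadata, frames = frames)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeVideoFile
#' @export
readVideoFile <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  t <- vapply(obj$frames, function(f) as.integer(f$time_ms), integer(1))
  mat <- do.call(rbind, lapply(obj$frames, function(f) {
    as.integer(unlist(f$settings))
  }))
  md <- obj$metadata
  if (is.null(md)) md <- list()
  new("VideoFile", timesMs = t, frames = mat, metadata = md)
}

#' Construct the ground truth of a simulated engine
#'
#' The default rig has ten Gaussian primaries with peaks evenly spaced
#' from 420 to 660 nm (FWHM 24 nm), a small broadband dark spectrum, and
#' a beta-CDF nonlinearity per channel mapping normalised 12-bit drive
#' (s/4095) to relative output.
#'
#' @param peaks 10 peak wavelengths (nm).
#' @param fwhm full width at half maximum of each primary (nm).
#' @param amplitudes 10 peak spectral irradiances (W m-2 nm-1).
#' @param alpha,beta 10 beta-CDF shape parameters (> 0); (1, 1) is a
#'   perfectly linear channel.
#' @param darkLevel constant dark spectral irradiance (W m-2 nm-1).
#' @param noiseSd per-wavelength Gaussian noise sd of the simulated
#'   output.
#' @param wl wavelength grid.
#' @return an \code{EngineGroundTruth}.
#' @export
engineGroundTruth <- function(peaks = seq(420, 660, length.out = 10),
                              fwhm = 24,
                              amplitudes = 0.02 * seq(0.8, 1.2,
                                                      length.out = 10),
                              alpha = rep(1, 10), beta = rep(1, 10),
                              darkLevel = 0, noiseSd = 0,
                              wl = defaultGrid()) {
  stopifnot(length(peaks) == 10L, length(amplitudes) == 10L)
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  primaries <- lapply(seq_len(10L), function(i) {
    Spectrum(wl, amplitudes[i] * exp(-0.5 * ((wl - peaks[i]) / sd)^2))
  })
  new("EngineGroundTruth", primaries = primaries, alpha = alpha,
      beta = beta, dark = Spectrum(wl, rep(darkLevel, length(wl))),
      noiseSd = noiseSd)
}

#' Read and write engine ground truth as YAML
#'
#' @param truth an \code{EngineGroundTruth}.
#' @param path file path.
#' @return \code{readEngineYaml} returns an \code{EngineGroundTruth}.
#' @export
writeEngineYaml <- function(truth, path) {
  obj <- list(
    wavelengths = truth@primaries[[1L]]@wavelengths,
    primaries = lapply(truth@primaries, function(p) p@values),
    alpha = truth@alpha, beta = truth@beta,
    dark = truth@dark@values, noise_sd = truth@noiseSd
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname writeEngineYaml
#' @export
readEngineYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  wl <- as.numeric(obj$wavelengths)
  new("EngineGroundTruth",
      primaries = lapply(obj$primaries, function(v) {
        Spectrum(wl, as.numeric(v))
      }),
      alpha = as.numeric(obj$alpha), beta = as.numeric(obj$beta),
      dark = Spectrum(wl, as.numeric(obj$dark)),
      noiseSd = as.numeric(obj$noise_sd))
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulated spectral output of the engine
#'
#' Forward model: dark spectrum plus the sum over channels of
#' \code{pbeta(s_i/4095, alpha_i, beta_i)} times the channel's primary,
#' plus per-wavelength Gaussian noise, clamped at zero.
#'
#' @param truth an \code{EngineGroundTruth}.
#' @param settings a \code{DeviceSettings}.
#' @param seed integer seed for the noise (ignored when noiseSd is 0);
#'   the caller's RNG state is left untouched.
#' @return a \code{Spectrum} (irradiance units).
#' @export
simulateOutput <- function(truth, settings, seed = NULL) {
  s <- intensities(settings)
  rel <- stats::pbeta(s / 4095, truth@alpha, truth@beta)
  wl <- truth@dark@wavelengths
  v <- truth@dark@values
  for (i in seq_len(10L)) {
    if (rel[i] > 0) v <- v + rel[i] * truth@primaries[[i]]@values
  }
  if (truth@noiseSd > 0) {
    v <- v + withLocalSeed(seed, stats::rnorm(length(v),
                                              sd = truth@noiseSd))
  }
  Spectrum(wl, v, units = "irradiance", clamp = TRUE)
}

#' Parameters of the simulated spectrometer
#'
#' The sensor model is \code{counts = irradiance * gain * integration_ms
#' + dark(temperature, integration) + noise}, with a dark offset linear
#' in both PCB temperature and integration time:
#' \code{dark = dark0 + darkPerC * temperature_C + darkPerMs *
#' integration_ms}. Shot noise is Gaussian with sd
#' \code{shotScale * sqrt(signal)} plus read noise \code{readSd}.
#' The same coefficients drive both the simulation and the dark/gain
#' correction applied during calibration.
#'
#' @param gain counts per (W m-2 nm-1 * ms).
#' @param dark0,darkPerC,darkPerMs dark-offset coefficients (counts).
#' @param shotScale,readSd noise coefficients (counts).
#' @param fullScale saturation level (counts).
#' @return a list of class \code{SpectrometerModel}.
#' @export
spectrometerModel <- function(gain = 4000, dark0 = 30, darkPerC = 0.5,
                              darkPerMs = 0.02, shotScale = 0,
                              readSd = 0, fullScale = 16383) {
  structure(list(gain = gain, dark0 = dark0, darkPerC = darkPerC,
                 darkPerMs = darkPerMs, shotScale = shotScale,
                 readSd = readSd, fullScale = fullScale),
            class = "SpectrometerModel")
}

# deterministic part of the dark reading (counts per sample)
darkOffset <- function(model, temperature_C, integration_ms) {
  model$dark0 + model$darkPerC * temperature_C +
    model$darkPerMs * integration_ms
}

#' Simulated spectrometer reading
#'
#' @param spectrum incident \code{Spectrum} (irradiance units).
#' @param integration_ms integration time (> 0).
#' @param temperature_C PCB temperature.
#' @param model a \code{SpectrometerModel}.
#' @param seed integer seed for the noise; the caller's RNG state is left
#'   untouched.
#' @return a counts-tagged \code{Spectrum}; metadata records integration
#'   time, temperature and a \code{saturated} flag when any sample
#'   exceeds full scale.
#' @export
simulateSpectrometer <- function(spectrum, integration_ms, temperature_C,
                                 model = spectrometerModel(),
                                 seed = NULL) {
  if (integration_ms <= 0) stop("integration_ms must be positive")
  signal <- spectrum@values * model$gain * integration_ms
  dark <- darkOffset(model, temperature_C, integration_ms)
  counts <- signal + dark
  if (model$shotScale > 0 || model$readSd > 0) {
    counts <- counts + withLocalSeed(seed, {
      stats::rnorm(length(counts),
                   sd = sqrt((model$shotScale * sqrt(pmax(signal, 0)))^2 +
                             model$readSd^2))
    })
  }
  saturated <- any(counts > model$fullScale)
  Spectrum(spectrum@wavelengths, counts, units = "counts",
           metadata = list(integration_ms = integration_ms,
                           temperature_C = temperature_C,
                           saturated = saturated),
           clamp = TRUE)
}
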