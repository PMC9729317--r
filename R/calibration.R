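#' @include engine.R photometry.R
NULL

#' Per-channel intensity sampling plan
#'
#' Multiples of \code{step} within the 12-bit range [1, 4095]. The
#' default step of 65 gives 63 evenly spaced levels per LED ending at
#' 4095 (63 * 65 = 4095). The zero level can be added explicitly; in a
#' dark-corrected pipeline the zero-drive output is zero by construction,
#' so it is usually anchored rather than measured.
#'
#' @param step integer step, 1 <= step <= 4095.
#' @param include_zero add level 0 to the plan.
#' @return integer vector of intensity levels.
#' @examples
#' length(samplingPlan())  # 63
#' @export
samplingPlan <- function(step = 65L, include_zero = FALSE) {
  step <- as.integer(step)
  if (is.na(step) || step < 1L || step > 4095L) {
    stop("step must be an integer in [1, 4095]")
  }
  plan <- seq.int(step, 4095L, by = step)
  if (include_zero) plan <- c(0L, plan)
  plan
}

#' Acquire a calibration table from the simulated rig
#'
#' For each LED channel and each level in the plan, drives that channel
#' alone, takes a simulated spectrometer reading, subtracts the
#' deterministic dark offset of the sensor model, divides by gain times
#' integration time to recover calibrated spectral irradiance, and clamps
#' at zero. Saturated readings are excluded with a message.
#'
#' @param truth an \code{EngineGroundTruth}.
#' @param plan integer levels, e.g. \code{samplingPlan()}.
#' @param integration_ms,temperature_C acquisition conditions.
#' @param model a \code{SpectrometerModel} (shared between simulation and
#'   correction).
#' @param seed integer; each reading gets a distinct sub-seed derived
#'   from it.
#' @return a \code{CalibrationTable}.
#' @export
acquireCalibration <- function(truth, plan = samplingPlan(),
                               integration_ms = 100, temperature_C = 25,
                               model = spectrometerModel(), seed = NULL) {
  wl <- truth@dark@wavelengths
  recs <- expand.grid(intensity = as.integer(plan), led = 0:9)
  keep <- logical(nrow(recs))
  spectra <- matrix(0, nrow(recs), length(wl))
  dark <- darkOffset(model, temperature_C, integration_ms)
  for (r in seq_len(nrow(recs))) {
    led <- recs$led[r]
    level <- recs$intensity[r]
    subSeed <- if (is.null(seed)) NULL else (seed + 1000L * led + level) %%
      .Machine$integer.max
    out <- simulateOutput(truth, singleChannelSettings(led, level),
                          seed = subSeed)
    reading <- simulateSpectrometer(out, integration_ms, temperature_C,
                                    model = model, seed = subSeed)
    if (isTRUE(reading@metadata$saturated)) {
      message(sprintf("excluding saturated reading: LED %d level %d",
                      led, level))
      next
    }
    # dark-correct (also removes the engine's dark spectrum term measured
    # through the same gain) and convert counts back to irradiance; the
    # symmetric measurement noise is kept (clamping at zero here would
    # bias low-intensity knots upward) -- spectra are clamped only when
    # materialised as Spectrum objects
    darkCounts <- dark + truth@dark@values * model$gain * integration_ms
    spectra[r, ] <- (reading@values - darkCounts) /
      (model$gain * integration_ms)
    keep[r] <- TRUE
  }
  new("CalibrationTable",
      led = as.integer(recs$led[keep]),
      intensity = as.integer(recs$intensity[keep]),
      wavelengths = wl, spectra = spectra[keep, , drop = FALSE])
}

#' Read and write a calibration table as long-format CSV
#'
#' Columns: led, intensity, wavelength_nm, value.
#'
#' @param table a \code{CalibrationTable}.
#' @param path file path.
#' @return \code{readCalibrationCsv} returns a \code{CalibrationTable}.
#' @export
writeCalibrationCsv <- function(table, path) {
  n <- length(table@led)
  nw <- length(table@wavelengths)
  df <- data.frame(
    led = rep(table@led, each = nw),
    intensity = rep(table@intensity, each = nw),
    wavelength_nm = rep(table@wavelengths, times = n),
    value = as.vector(t(table@spectra))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibrationCsv
#' @export
readCalibrationCsv <- function(path) {
  df <- utils::read.csv(path)
  wl <- sort(unique(df$wavelength_nm))
  key <- paste(df$led, df$intensity)
  ukey <- unique(key)
  led <- integer(length(ukey))
  intensity <- integer(length(ukey))
  spectra <- matrix(0, length(ukey), length(wl))
  for (i in seq_along(ukey)) {
    sub <- df[key == ukey[i], ]
    sub <- sub[order(sub$wavelength_nm), ]
    led[i] <- sub$led[1L]
    intensity[i] <- sub$intensity[1L]
    spectra[i, ] <- sub$value
  }
  new("CalibrationTable", led = led, intensity = intensity,
      wavelengths = wl, spectra = spectra)
}

#' Build a calibration context from a table
#'
#' Per channel, measured spectra become interpolation knots over
#' intensity. A missing zero level is anchored at (0, zero spectrum) --
#' dark-corrected output at zero drive is physically zero -- with a
#' message. Dense 0-4095 lookup tables of photopic illuminance,
#' alpha-opic irradiances and unweighted irradiance are derived from the
#' interpolated spectra (equivalently, by interpolating the knot scalars,
#' since every one is a linear functional of the spectrum).
#'
#' @param table a \code{CalibrationTable} with >= 2 levels per LED
#'   (counting the zero anchor).
#' @return a \code{CalibrationContext}.
#' @export
buildContext <- function(table) {
  wl <- table@wavelengths
  grid <- 0:4095
  knotI <- vector("list", 10L)
  knotS <- vector("list", 10L)
  lux <- matrix(0, 4096L, 10L)
  irr <- matrix(0, 4096L, 10L)
  aop <- array(0, c(4096L, 10L, 5L))
  step <- gridStep(wl)
  vWeights <- stats::approx(weightingFunction("photopic")$wavelengths,
                            weightingFunction("photopic")$weights,
                            xout = wl, yleft = 0, yright = 0)$y
  aWeights <- vapply(aopicNames(), function(nm) {
    w <- weightingFunction(nm)
    stats::approx(w$wavelengths, w$weights, xout = wl,
                  yleft = 0, yright = 0)$y
  }, numeric(length(wl)))
  for (led in 0:9) {
    idx <- which(table@led == led)
    levels <- table@intensity[idx]
    o <- order(levels)
    levels <- levels[o]
    spec <- table@spectra[idx[o], , drop = FALSE]
    if (!length(levels) || levels[1L] != 0L) {
      message(sprintf("LED %d: anchoring interpolation at (0, zero)", led))
      levels <- c(0L, levels)
      spec <- rbind(rep(0, length(wl)), spec)
    }
    if (length(levels) < 2L) {
      stop(sprintf("LED %d: need at least 2 levels to interpolate", led))
    }
    knotI[[led + 1L]] <- as.integer(levels)
    knotS[[led + 1L]] <- spec
    knotLux <- 683 * step * as.vector(spec %*% vWeights)
    knotIrr <- step * rowSums(spec)
    knotAop <- step * (spec %*% aWeights)
    lux[, led + 1L] <- stats::approx(levels, knotLux, xout = grid,
                                     rule = 2)$y
    irr[, led + 1L] <- stats::approx(levels, knotIrr, xout = grid,
                                     rule = 2)$y
    for (k in 1:5) {
      aop[, led + 1L, k] <- stats::approx(levels, knotAop[, k],
                                          xout = grid, rule = 2)$y
    }
  }
  dimnames(aop) <- list(NULL, NULL, aopicNames())
  new("CalibrationContext", wavelengths = wl, knotIntensities = knotI,
      knotSpectra = knotS, lux = lux, irradiance = irr, aopic = aop)
}

#' Interpolated per-channel spectrum at any 12-bit level
#'
#' @param ctx a \code{CalibrationContext}.
#' @param led channel index 0-9.
#' @param intensity level in [0, 4095] (may be fractional).
#' @return a \code{Spectrum} (irradiance units).
#' @export
contextSpectrum <- function(ctx, led, intensity) {
  if (intensity < 0 || intensity > 4095) stop("intensity out of range")
  k <- ctx@knotIntensities[[led + 1L]]
  s <- ctx@knotSpectra[[led + 1L]]
  if (intensity <= k[1L]) return(Spectrum(ctx@wavelengths, s[1L, ]))
  if (intensity >= k[length(k)]) {
    return(Spectrum(ctx@wavelengths, s[length(k), ]))
  }
  j <- findInterval(intensity, k)
  f <- (intensity - k[j]) / (k[j + 1L] - k[j])
  Spectrum(ctx@wavelengths, (1 - f) * s[j, ] + f * s[j + 1L, ],
           clamp = TRUE)
}

#' Lookup derived quantities per channel and level
#'
#' @param ctx a \code{CalibrationContext}.
#' @param led channel index 0-9.
#' @param intensity integer level 0-4095.
#' @return \code{contextLux}: photopic illuminance (lx);
#'   \code{contextAopic}: named 5-vector; \code{contextIrradiance}:
#'   unweighted integrated irradiance.
#' @export
contextLux <- function(ctx, led, intensity) {
  ctx@lux[as.integer(intensity) + 1L, led + 1L]
}

#' @rdname contextLux
#' @export
contextAopic <- function(ctx, led, intensity) {
  ctx@aopic[as.integer(intensity) + 1L, led + 1L, ]
}

#' @rdname contextLux
#' @export
contextIrradiance <- function(ctx, led, intensity) {
  ctx@irradiance[as.integer(intensity) + 1L, led + 1L]
}

#' Predict the spectral output for arbitrary device settings
#'
#' Sum over channels of the per-channel interpolated spectrum at each
#' setting (the additivity assumption of a multiprimary engine).
#'
#' @param ctx a \code{CalibrationContext}.
#' @param settings a \code{DeviceSettings}.
#' @return a \code{Spectrum} (irradiance units, dark-corrected
#'   convention: all-zero settings give the zero spectrum).
#' @export
predictSpd <- function(ctx, settings) {
  s <- intensities(settings)
  v <- rep(0, length(ctx@wavelengths))
  for (led in 0:9) {
    if (s[led + 1L] > 0) {
      v <- v + contextSpectrum(ctx, led, s[led + 1L])@values
    }
  }
  Spectrum(ctx@wavelengths, v)
}

#' Fit beta-CDF linearisation curves to the calibrated channels
#'
#' Per channel, fits \code{pbeta(s/4095, alpha, beta)} to normalised
#' illuminance (lux at the knots divided by lux at 4095) by unweighted
#' least squares over (log alpha, log beta).
#'
#' @param ctx a \code{CalibrationContext}.
#' @return a \code{data.frame} with columns \code{led}, \code{alpha},
#'   \code{beta}, \code{scale} (max illuminance, lx).
#' @export
fitCurves <- function(ctx) {
  out <- data.frame(led = 0:9, alpha = NA_real_, beta = NA_real_,
                    scale = NA_real_)
  for (led in 0:9) {
    k <- ctx@knotIntensities[[led + 1L]]
    y <- ctx@lux[k + 1L, led + 1L]
    ymax <- ctx@lux[4096L, led + 1L]
    if (ymax <= 0) {
      stop(sprintf("LED %d: zero output, cannot fit a curve", led))
    }
    x <- k / 4095
    yn <- y / ymax
    obj <- function(p) sum((stats::pbeta(x, exp(p[1L]), exp(p[2L])) -
                              yn)^2)
    fit <- stats::optim(c(0, 0), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (fit$convergence != 0) {
      stop(sprintf("LED %d: beta-CDF fit did not converge", led))
    }
    out$alpha[led + 1L] <- exp(fit$par[1L])
    out$beta[led + 1L] <- exp(fit$par[2L])
    out$scale[led + 1L] <- ymax
  }
  out
}

#' Correct a relative stimulus profile for channel nonlinearity
#'
#' Given desired relative outputs in [0, 1] per channel, inverts each
#' fitted beta CDF and quantises to 12-bit settings, so that pushing the
#' result back through the fitted curve reproduces the desired relative
#' output within quantisation error.
#'
#' @param curves the \code{data.frame} from \code{\link{fitCurves}}.
#' @param desired numeric(10) of relative outputs in [0, 1].
#' @return a \code{DeviceSettings}.
#' @examples
#' curves <- data.frame(led = 0:9, alpha = 1, beta = 1, scale = 100)
#' optimiseProfile(curves, rep(0.5, 10))  # 2048 everywhere
#' @export
optimiseProfile <- function(curves, desired) {
  stopifnot(length(desired) == 10L)
  if (any(desired < 0 | desired > 1)) {
    stop("desired relative outputs must be in [0, 1]")
  }
  s <- round(4095 * stats::qbeta(desired, curves$alpha, curves$beta))
  deviceSettings(s)
}

#' Persist and restore a calibration context
#'
#' Directory layout: one long-format CSV of the knot spectra
#' (\code{knots.csv}, as in \code{\link{writeCalibrationCsv}}) plus the
#' fitted curve parameters as YAML when supplied. Restoring rebuilds the
#' dense lookups from the knots.
#'
#' @param ctx a \code{CalibrationContext}.
#' @param dir directory path.
#' @param curves optional \code{data.frame} from \code{\link{fitCurves}}.
#' @return \code{readContext} returns a list with elements \code{ctx} and
#'   \code{curves} (NULL when absent).
#' @export
writeContext <- function(ctx, dir, curves = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  led <- integer(0); intensity <- integer(0); rows <- list()
  for (i in 0:9) {
    k <- ctx@knotIntensities[[i + 1L]]
    led <- c(led, rep(i, length(k)))
    intensity <- c(intensity, k)
    rows[[i + 1L]] <- ctx@knotSpectra[[i + 1L]]
  }
  tab <- new("CalibrationTable", led = led, intensity = intensity,
             wavelengths = ctx@wavelengths, spectra = do.call(rbind, rows))
  writeCalibrationCsv(tab, file.path(dir, "knots.csv"))
  if (!is.null(curves)) {
    yaml::write_yaml(as.list(curves), file.path(dir, "curves.yaml"))
  }
  invisible(dir)
}

#' @rdname writeContext
#' @export
readContext <- function(dir) {
  tab <- readCalibrationCsv(file.path(dir, "knots.csv"))
  curvesPath <- file.path(dir, "curves.yaml")
  curves <- NULL
  if (file.exists(curvesPath)) {
    curves <- as.data.frame(yaml::read_yaml(curvesPath))
  }
  list(ctx = buildContext(tab), curves = curves)
}
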