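# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# noiseless linear engine and its calibrated context
linearContext <- function() {
  if (is.null(.fixtures$linCtx)) {
    truth <- engineGroundTruth()  # alpha = beta = 1: linear channels
    tab <- acquireCalibration(truth, samplingPlan(), seed = 101L)
    .fixtures$linTruth <- truth
    .fixtures$linCtx <- suppressMessages(buildContext(tab))
  }
  list(truth = .fixtures$linTruth, ctx = .fixtures$linCtx)
}

# noiseless engine with a known (2, 3) beta-CDF nonlinearity
curvedContext <- function() {
  if (is.null(.fixtures$curveCtx)) {
    truth <- engineGroundTruth(alpha = rep(2, 10), beta = rep(3, 10))
    tab <- acquireCalibration(truth, samplingPlan(), seed = 202L)
    .fixtures$curveTruth <- truth
    .fixtures$curveCtx <- suppressMessages(buildContext(tab))
  }
  list(truth = .fixtures$curveTruth, ctx = .fixtures$curveCtx)
}

# a Gaussian test spectrum on the default grid
gaussianSpectrum <- function(center = 500, sd = 30, amp = 1,
                             units = "irradiance") {
  wl <- defaultGrid()
  Spectrum(wl, amp * exp(-0.5 * ((wl - center) / sd)^2), units = units)
}

# monochromatic line of given power per nm at one grid wavelength
monoSpectrum <- function(at, power = 1, units = "irradiance") {
  wl <- defaultGrid()
  Spectrum(wl, ifelse(wl == at, power, 0), units = units)
}
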