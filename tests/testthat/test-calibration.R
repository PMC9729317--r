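test_that("the sampling plan covers the 12-bit range in even steps", {
  plan <- samplingPlan()
  expect_length(plan, 63L)
  expect_equal(plan[length(plan)], 4095L)
  expect_equal(diff(plan), rep(65L, 62L))
  expect_equal(samplingPlan(4095), 4095L)
  expect_equal(samplingPlan(1024), c(1024L, 2048L, 3072L))
  expect_equal(samplingPlan(65, include_zero = TRUE)[1L], 0L)
  expect_error(samplingPlan(0), "step")
  expect_error(samplingPlan(5000), "step")
})

test_that("acquisition recovers calibrated irradiance from raw counts", {
  fx <- linearContext()
  tab <- acquireCalibration(fx$truth, c(2048L), seed = 1L)
  i <- which(tab@led == 4L & tab@intensity == 2048L)
  expect_equal(tab@spectra[i, ],
               (2048 / 4095) * spectrumValues(fx$truth@primaries[[5]]),
               tolerance = 1e-9)
  # a null primary yields all-zero spectra after dark correction
  dead <- engineGroundTruth(amplitudes = c(0, rep(0.02, 9)))
  tabDead <- acquireCalibration(dead, c(1000L, 4095L), seed = 1L)
  expect_equal(max(tabDead@spectra[tabDead@led == 0L, ]), 0)
  # determinism under a fixed seed
  noisy <- engineGroundTruth(noiseSd = 1e-4)
  t1 <- acquireCalibration(noisy, c(65L, 130L), seed = 9L)
  t2 <- acquireCalibration(noisy, c(65L, 130L), seed = 9L)
  expect_identical(t1@spectra, t2@spectra)
})

test_that("calibration tables round-trip through long-format CSV", {
  fx <- linearContext()
  tab <- acquireCalibration(fx$truth, c(1000L, 4095L), seed = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCalibrationCsv(tab, path)
  back <- readCalibrationCsv(path)
  for (led in c(0L, 9L)) {
    i1 <- which(tab@led == led & tab@intensity == 4095L)
    i2 <- which(back@led == led & back@intensity == 4095L)
    expect_equal(back@spectra[i2, ], tab@spectra[i1, ], tolerance = 1e-12)
  }
})

test_that("the context interpolates linearly between measured knots", {
  fx <- linearContext()
  tab <- acquireCalibration(fx$truth,
                            samplingPlan(4095, include_zero = TRUE),
                            seed = 1L)
  ctx <- suppressMessages(buildContext(tab))
  top <- tab@spectra[which(tab@led == 2L & tab@intensity == 4095L), ]
  # exact midpoint of the {0, 4095} knots is the average of the endpoints
  mid <- contextSpectrum(ctx, 2, 4095 / 2)
  expect_equal(spectrumValues(mid), (0 + top) / 2, tolerance = 1e-9)
  # at a measured knot the measured spectrum comes back exactly
  full <- linearContext()$ctx
  knot <- contextSpectrum(full, 6, 650)  # 650 = 10 * 65, a plan level
  expect_equal(
    spectrumValues(knot),
    (650 / 4095) * spectrumValues(fx$truth@primaries[[7]]),
    tolerance = 1e-9)
})

test_that("lux lookups of a monotone simulator are non-decreasing", {
  fx <- curvedContext()
  for (led in 0:9) {
    expect_true(all(diff(fx$ctx@lux[, led + 1L]) >= -1e-12))
  }
})

test_that("predicted spectra match the noiseless simulator", {
  fx <- linearContext()
  expect_equal(max(spectrumValues(predictSpd(fx$ctx, darkSettings()))), 0)
  # one channel at a calibration level returns that calibration spectrum
  one <- predictSpd(fx$ctx, singleChannelSettings(0, 1300))  # 20 * 65
  expect_equal(spectrumValues(one),
               (1300 / 4095) * spectrumValues(fx$truth@primaries[[1]]),
               tolerance = 1e-9)
  # 20 random settings: total-irradiance error below 1%
  set.seed(123)
  relErr <- vapply(1:20, function(i) {
    s <- deviceSettings(sample(0:4095, 10, replace = TRUE))
    pred <- totalIrradiance(predictSpd(fx$ctx, s))
    truth <- totalIrradiance(simulateOutput(fx$truth, s))
    abs(pred - truth) / truth
  }, numeric(1))
  expect_lt(max(relErr), 0.01)
})

test_that("beta-CDF fits recover channel nonlinearity", {
  lin <- linearContext()
  cvLin <- fitCurves(lin$ctx)
  expect_equal(cvLin$alpha, rep(1, 10), tolerance = 1e-3)
  expect_equal(cvLin$beta, rep(1, 10), tolerance = 1e-3)
  crv <- curvedContext()
  cv <- fitCurves(crv$ctx)
  expect_equal(cv$alpha, rep(2, 10), tolerance = 1e-3)
  expect_equal(cv$beta, rep(3, 10), tolerance = 1e-3)
  expect_equal(cv$scale, crv$ctx@lux[4096L, ], tolerance = 1e-12)
})

test_that("fits stay within 5% under ~1% sensor noise", {
  # a photometrically balanced rig (peaks where V(lambda) is
  # appreciable) so one read-noise level means ~1% CV on every
  # channel's mid-range illuminance; 45 counts of read noise on top of
  # a 600-count dark offset gives that CV
  truth <- engineGroundTruth(peaks = seq(500, 600, length.out = 10),
                             alpha = rep(2, 10), beta = rep(3, 10))
  noisy <- spectrometerModel(readSd = 45, dark0 = 600)
  aErr <- bErr <- matrix(0, 20, 10)
  for (seed in 1:20) {
    tab <- acquireCalibration(truth, samplingPlan(), model = noisy,
                              seed = seed)
    ctx <- suppressMessages(buildContext(tab))
    cv <- fitCurves(ctx)
    aErr[seed, ] <- abs(cv$alpha - 2) / 2
    bErr[seed, ] <- abs(cv$beta - 3) / 3
  }
  # Monte-Carlo recovery on a mid channel, and sanity across the rig
  expect_lt(max(aErr[, 5]), 0.05)
  expect_lt(max(bErr[, 5]), 0.05)
  expect_lt(mean(aErr), 0.05)
  expect_lt(mean(bErr), 0.05)
  expect_lt(max(aErr), 0.10)
  expect_lt(max(bErr), 0.10)
})

test_that("profile optimisation inverts the fitted nonlinearity", {
  curves <- data.frame(led = 0:9, alpha = 1, beta = 1, scale = 100)
  expect_equal(intensities(optimiseProfile(curves, rep(0, 10))),
               rep(0L, 10L))
  expect_equal(intensities(optimiseProfile(curves, rep(1, 10))),
               rep(4095L, 10L))
  expect_equal(intensities(optimiseProfile(curves, rep(0.5, 10))),
               rep(2048L, 10L))
  crv <- curvedContext()
  cv <- fitCurves(crv$ctx)
  s <- optimiseProfile(cv, rep(0.5, 10))
  forward <- pbeta(intensities(s) / 4095, cv$alpha, cv$beta)
  expect_lt(max(abs(forward - 0.5)), 1 / 4095)
  # round-trip across the usable range
  for (targetRel in c(0.01, 0.1, 0.5, 0.9, 0.99)) {
    s <- optimiseProfile(cv, rep(targetRel, 10))
    fwd <- pbeta(intensities(s) / 4095, cv$alpha, cv$beta)
    expect_lt(max(abs(fwd - targetRel)), 2 / 4095)
  }
  expect_error(optimiseProfile(cv, rep(1.2, 10)), "0, 1")
})

test_that("lookup error shrinks ~quadratically with plan step", {
  truth <- engineGroundTruth(alpha = rep(2, 10), beta = rep(3, 10))
  errAt <- function(step) {
    tab <- acquireCalibration(truth, samplingPlan(step), seed = 1L)
    ctx <- suppressMessages(buildContext(tab))
    probe <- seq(100L, 3995L, by = 130L)
    max(vapply(probe, function(lev) {
      pred <- contextLux(ctx, 4, lev)
      tru <- photopicIlluminance(simulateOutput(truth,
               singleChannelSettings(4, lev)))
      abs(pred - tru)
    }, numeric(1)))
  }
  e1 <- errAt(512)
  e2 <- errAt(256)
  order <- log2(e1 / e2)
  expect_gt(order, 1.8)
})

test_that("contexts persist and restore with their curves", {
  fx <- curvedContext()
  cv <- fitCurves(fx$ctx)
  dir <- withr::local_tempdir()
  writeContext(fx$ctx, dir, curves = cv)
  back <- suppressMessages(readContext(dir))
  expect_equal(back$ctx@lux, fx$ctx@lux, tolerance = 1e-6)
  expect_equal(back$curves$alpha, cv$alpha, tolerance = 1e-6)
  s <- deviceSettings(rep(1000, 10))
  expect_equal(spectrumValues(predictSpd(back$ctx, s)),
               spectrumValues(predictSpd(fx$ctx, s)), tolerance = 1e-6)
})

test_that("a channel with a single level cannot build a context", {
  fx <- linearContext()
  tab <- acquireCalibration(fx$truth, c(4095L), seed = 1L)
  one <- new("CalibrationTable", led = tab@led[tab@led == 0L],
             intensity = tab@intensity[tab@led == 0L],
             wavelengths = tab@wavelengths,
             spectra = tab@spectra[tab@led == 0L, , drop = FALSE])
  # LED 0 has the zero anchor + one level (fine); LEDs 1-9 have nothing
  expect_error(suppressMessages(buildContext(one)), "at least 2 levels")
})
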