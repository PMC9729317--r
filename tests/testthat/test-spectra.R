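test_that("Spectrum validity enforces grid and value invariants", {
  expect_s4_class(Spectrum(380:780, rep(1, 401)), "Spectrum")
  expect_error(Spectrum(c(400, 400, 410), c(1, 1, 1)), "increasing")
  expect_error(Spectrum(400:402, c(1, NA, 1)), "finite")
  expect_error(Spectrum(400:402, c(1, -1, 1)), "non-negative")
  expect_error(Spectrum(400:401, c(1, 1), units = "lumens"), "units")
})

test_that("resampling is the identity on the source grid and preserves
           constants", {
  s <- gaussianSpectrum()
  expect_equal(spectrumValues(resampleSpectrum(s, defaultGrid())),
               spectrumValues(s))
  const <- Spectrum(380:780, rep(2, 401))
  sub <- resampleSpectrum(const, seq(400, 700, 5))
  expect_equal(spectrumValues(sub), rep(2, 61))
  expect_error(resampleSpectrum(s, c(500, 400)), "increasing")
})

test_that("resampling a coarse triangle reproduces the linear segment", {
  # triangle apex 1 at 500 nm, base 480-520, sampled every 10 nm
  coarseWl <- seq(380, 780, 10)
  tri <- pmax(0, 1 - abs(coarseWl - 500) / 20)
  s <- Spectrum(coarseWl, tri)
  fine <- resampleSpectrum(s, defaultGrid())
  # at 505 nm the 10 nm samples bracket (500, 1) and (510, 0.5):
  # the interpolant, like the true triangle, gives 0.75
  expect_equal(spectrumValues(fine)[defaultGrid() == 505], 0.75)
  # outside the source support the power is zero by convention
  narrow <- Spectrum(500:600, rep(1, 101))
  wide <- resampleSpectrum(narrow, defaultGrid())
  expect_equal(spectrumValues(wide)[defaultGrid() < 500], rep(0, 120))
})

test_that("weighted integral follows the rectangle-rule convention", {
  z <- Spectrum(defaultGrid(), rep(0, 401))
  w <- narrowbandWeighting(500, 50)
  expect_equal(weightedIntegral(z, w), 0)
  # unit spectrum x unit weight over 400-500 at 1 nm: 101 samples x 1 nm
  s <- Spectrum(400:500, rep(1, 101))
  wUnit <- structure(list(name = "unit", wavelengths = 400:500,
                          weights = rep(1, 101)),
                     class = "WeightingFunction")
  expect_equal(weightedIntegral(s, wUnit), 101)
  # disjoint supports give zero with a warning
  blue <- Spectrum(380:430, rep(1, 51))
  redW <- structure(list(name = "red", wavelengths = 600:700,
                         weights = rep(1, 101)),
                    class = "WeightingFunction")
  expect_warning(v <- weightedIntegral(blue, redW), "disjoint")
  expect_equal(v, 0)
})

test_that("weighted integral matches an independent loop-summation oracle", {
  wl <- defaultGrid()
  gaussW <- structure(list(name = "gw", wavelengths = wl,
                           weights = exp(-0.5 * ((wl - 520) / 40)^2)),
                      class = "WeightingFunction")
  loopSum <- function(v, w, step) {
    acc <- 0
    for (i in seq_along(v)) acc <- acc + v[i] * w[i] * step
    acc
  }
  set.seed(11)
  for (rep in 1:50) {
    v <- runif(401)
    s <- Spectrum(wl, v)
    expect_equal(weightedIntegral(s, gaussW),
                 loopSum(v, gaussW$weights, 1), tolerance = 1e-10)
  }
  # Gaussian spectrum x Gaussian weight against the same oracle
  g <- gaussianSpectrum(480, 25)
  expect_equal(weightedIntegral(g, gaussW),
               loopSum(spectrumValues(g), gaussW$weights, 1),
               tolerance = 1e-9)
})

test_that("weighted integrals are linear in the spectrum", {
  w <- weightingFunction("melanopic")
  set.seed(7)
  for (rep in 1:10) {
    v1 <- runif(401); v2 <- runif(401); c1 <- runif(1, 0.1, 10)
    s1 <- Spectrum(defaultGrid(), v1)
    s2 <- Spectrum(defaultGrid(), v2)
    sSum <- Spectrum(defaultGrid(), c1 * v1 + v2)
    expect_equal(weightedIntegral(sSum, w),
                 c1 * weightedIntegral(s1, w) + weightedIntegral(s2, w),
                 tolerance = 1e-12)
  }
})

test_that("alpha-opic irradiance behaves physically", {
  expect_equal(unname(aopicIrradiance(Spectrum(defaultGrid(),
                                               rep(0, 401)))),
               rep(0, 5))
  # deep red light drives L cones, barely melanopsin
  a <- aopicIrradiance(monoSpectrum(660))
  expect_lt(a[["melanopic"]], 0.01 * a[["L-cone-opic"]])
  # homogeneity of degree 1
  s <- gaussianSpectrum()
  expect_equal(aopicIrradiance(scaleSpectrum(s, 2)),
               2 * aopicIrradiance(s), tolerance = 1e-12)
  # counts-tagged input is rejected
  expect_error(aopicIrradiance(gaussianSpectrum(units = "counts")),
               "irradiance")
})

test_that("adding power never decreases any alpha-opic component", {
  set.seed(3)
  for (rep in 1:20) {
    v <- runif(401)
    at <- sample(401, 1)
    bumped <- v; bumped[at] <- bumped[at] + runif(1, 0, 5)
    a0 <- aopicIrradiance(Spectrum(defaultGrid(), v))
    a1 <- aopicIrradiance(Spectrum(defaultGrid(), bumped))
    expect_true(all(a1 >= a0 - 1e-12))
  }
})

test_that("photopic illuminance reproduces the lumen definition", {
  expect_equal(photopicIlluminance(Spectrum(defaultGrid(),
                                            rep(0, 401))), 0)
  # 1 W m-2 of monochromatic 555 nm light is ~683 lx
  expect_equal(photopicIlluminance(monoSpectrum(555)), 683,
               tolerance = 0.01)
  s <- gaussianSpectrum()
  expect_equal(photopicIlluminance(scaleSpectrum(s, 3.7)),
               3.7 * photopicIlluminance(s), tolerance = 1e-12)
})

test_that("chromaticity is projective and places known points", {
  ee <- Spectrum(defaultGrid(), rep(1, 401))
  xy <- chromaticityXY(ee)
  expect_equal(unname(xy), c(1 / 3, 1 / 3), tolerance = 0.02)
  s <- gaussianSpectrum(600, 20)
  expect_equal(chromaticityXY(scaleSpectrum(s, 12)), chromaticityXY(s),
               tolerance = 1e-12)
  # a narrowband line sits on the spectral locus of the embedded CMFs
  cx <- weightingFunction("cie-x")
  cy <- weightingFunction("cie-y")
  cz <- weightingFunction("cie-z")
  i <- which(cx$wavelengths == 470)
  locus <- c(cx$weights[i], cy$weights[i], cz$weights[i])
  locus <- locus[1:2] / sum(locus)
  expect_equal(unname(chromaticityXY(monoSpectrum(470))), locus,
               tolerance = 1e-9)
  expect_error(chromaticityXY(Spectrum(defaultGrid(), rep(0, 401))),
               "zero")
})

test_that("melanopic weighting peaks in the 480-500 nm band", {
  mel <- weightingFunction("melanopic")
  peak <- mel$wavelengths[which.max(mel$weights)]
  expect_gt(peak, 480)
  expect_lt(peak, 500)
})

test_that("pupil correction factor is the squared diameter ratio", {
  expect_equal(pupilCorrectionFactor(7), (7 / 3)^2)  # prints as 5.4
  expect_equal(floor(pupilCorrectionFactor(7) * 10) / 10, 5.4)
  expect_equal(pupilCorrectionFactor(3), 1)
  expect_equal(pupilCorrectionFactor(6), 4)
  expect_error(pupilCorrectionFactor(0), "positive")
})

test_that("blue-light hazard applies the correct limits", {
  z <- Spectrum(defaultGrid(), rep(0, 401), units = "radiance")
  h <- blueLightHazard(z, 5000)
  expect_equal(h$lB, 0)
  expect_true(h$withinLimit)
  expect_equal(h$baseLimit, 1e6 / 5000)
  # long exposure, fully dilated pupil: limit drops from 100 to 16.6
  h6 <- blueLightHazard(z, 2e4, pupil_correction_factor = 6)
  expect_equal(h6$exposureLimit, 100 / 6)
  expect_match(paste(capture.output(print(h6)), collapse = "\n"), "16.6",
               fixed = TRUE)
  # a line at the B(lambda) maximum: single-term sum
  bw <- weightingFunction("blue-light-hazard")
  bmaxWl <- bw$wavelengths[which.max(bw$weights)]
  r <- 3.5
  line <- Spectrum(defaultGrid(),
                   ifelse(defaultGrid() == bmaxWl, r, 0),
                   units = "radiance")
  h1 <- blueLightHazard(line, 2e4)
  expect_equal(h1$lB, r * max(bw$weights) * 1)
  expect_error(blueLightHazard(gaussianSpectrum(), 10), "radiance")
})

test_that("the within-limit verdict flips exactly at the limit", {
  bw <- weightingFunction("blue-light-hazard")
  bmaxWl <- bw$wavelengths[which.max(bw$weights)]
  mk <- function(r) Spectrum(defaultGrid(),
                             ifelse(defaultGrid() == bmaxWl, r, 0),
                             units = "radiance")
  lim <- 100  # t > 1e4 s, factor 1
  expect_true(blueLightHazard(mk(lim * (1 - 1e-9)), 2e4)$withinLimit)
  expect_false(blueLightHazard(mk(lim * (1 + 1e-9)), 2e4)$withinLimit)
})

test_that("spectra round-trip through CSV with their units tag", {
  s <- gaussianSpectrum(units = "radiance")
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectrumCsv(s, path)
  back <- readSpectrumCsv(path)
  expect_equal(spectrumValues(back), spectrumValues(s))
  expect_equal(unitsTag(back), "radiance")
})
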