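# steady-state amplitude of a filtered sinusoid, estimated on the
# middle of the trace by least squares against a sin/cos basis
fittedAmplitude <- function(y, t, freq) {
  mid <- t > quantile(t, 0.25) & t < quantile(t, 0.75)
  X <- cbind(sin(2 * pi * freq * t[mid]), cos(2 * pi * freq * t[mid]))
  beta <- qr.solve(X, y[mid])
  sqrt(sum(beta^2))
}

test_that("eye selection picks the higher-confidence eye", {
  rec <- data.frame(eye_id = c(0, 0, 1, 1),
                    confidence = c(0.99, 0.99, 0.90, 0.90))
  expect_equal(selectEye(rec), 0L)
  expect_equal(selectEye(data.frame(eye_id = 1, confidence = 0.5)), 1L)
  tie <- data.frame(eye_id = c(0, 1), confidence = c(0.9, 0.9))
  expect_equal(selectEye(tie), 0L)
  set.seed(5)
  m0 <- runif(1, 0.5, 1); m1 <- runif(1, 0.5, 1)
  planted <- data.frame(eye_id = rep(c(0, 1), each = 100),
                        confidence = c(rnorm(100, m0, 0.01),
                                       rnorm(100, m1, 0.01)))
  expect_equal(selectEye(planted),
               as.integer(which.max(c(mean(planted$confidence[1:100]),
                                      mean(planted$confidence[101:200])))
                          - 1L))
  expect_error(selectEye(data.frame(eye_id = integer(0),
                                    confidence = numeric(0))), "records")
})

test_that("artifact masking applies the derivative and confidence
           rules", {
  t <- (0:199) / 100
  smooth <- 5 + 0.1 * sin(t)
  clean <- maskArtifacts(t, smooth, rep(1, 200))
  expect_equal(clean$report$total, 0L)
  expect_equal(clean$values, smooth)
  # a single step spike produces two outlying differences; the samples
  # carrying them (the spike and its right neighbour) are masked
  spiked <- smooth
  spiked[100] <- spiked[100] + 3
  m <- maskArtifacts(t, spiked, rep(1, 200))
  expect_equal(m$report$by_derivative, 2L)
  expect_true(all(is.na(m$values[c(100, 101)])))
  # confidence below 0.95 is masked, at 0.95 retained (strict <)
  conf <- rep(1, 200)
  low <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 110)
  conf[low] <- 0.94
  conf[120] <- 0.95
  m2 <- maskArtifacts(t, smooth, conf)
  expect_equal(m2$report$by_confidence, 10L)
  expect_true(all(is.na(m2$values[low])))
  expect_false(is.na(m2$values[120]))
  expect_error(maskArtifacts(t[1:2], smooth[1:2]), "3 samples")
})

test_that("the mask report counts are conserved", {
  set.seed(9)
  t <- (0:499) / 120
  v <- 5 + cumsum(rnorm(500, 0, 0.01))
  v[c(50, 250)] <- v[c(50, 250)] + 2
  conf <- rep(1, 500)
  conf[c(50, 51, 300:310)] <- 0.5
  m <- maskArtifacts(t, v, conf)
  expect_equal(m$report$by_derivative + m$report$by_confidence -
                 m$report$by_both, m$report$total)
  expect_gt(m$report$by_both, 0L)
})

test_that("linear interpolation reconstructs gaps and edges", {
  t <- 0:10
  v <- c(4, NA, 6, 7, 8, 9, 10, 11, 12, 13, 14)
  expect_equal(interpolateMissing(t, v)[2], 5)
  full <- as.numeric(1:11)
  expect_equal(interpolateMissing(t, full), full)
  # linear traces are fixed points under random masking
  set.seed(13)
  line <- 2.5 * (0:199) / 50 + 1
  masked <- line
  masked[sample(2:199, 10)] <- NA
  expect_equal(interpolateMissing((0:199) / 50, masked), line,
               tolerance = 1e-12)
  # edge gaps take the nearest valid value
  v2 <- c(NA, NA, 3, 4, NA)
  expect_equal(interpolateMissing(0:4, v2), c(3, 3, 3, 4, 4))
  expect_error(interpolateMissing(0:2, rep(NA_real_, 3)), "missing")
})

test_that("zero-phase Butterworth smoothing has the documented
           magnitude response", {
  rate <- 120
  t <- seq(0, 20, by = 1 / rate)
  expect_equal(lowpassFilter(rep(5, length(t)), rate), rep(5, length(t)),
               tolerance = 1e-6)
  # at the 4 Hz cutoff the two passes square |H| to 1/2
  y4 <- lowpassFilter(sin(2 * pi * 4 * t), rate)
  expect_equal(fittedAmplitude(y4, t, 4), 0.5, tolerance = 0.02)
  # analytic |H(f)|^2 = 1 / (1 + (f/4)^6) off the cutoff, measured at a
  # sampling rate high enough that bilinear frequency warping is
  # negligible
  rateHi <- 1000
  tHi <- seq(0, 20, by = 1 / rateHi)
  for (f in c(1, 2, 8, 10)) {
    y <- lowpassFilter(sin(2 * pi * f * tHi), rateHi)
    expect_equal(fittedAmplitude(y, tHi, f), 1 / (1 + (f / 4)^6),
                 tolerance = 0.02)
  }
  expect_error(lowpassFilter(rep(1, 100), 8, cutoff_hz = 4), "Nyquist")
})

test_that("filtering preserves length, and the clean pipeline is
           idempotent on in-band data", {
  g <- generatePlr(plrSpec(noise_sd_mm = 0, blink_rate_hz = 0))
  t <- g$records$pupil_timestamp
  v <- g$records$diameter_3d
  once <- cleanPupilSeries(t, v, g$records$confidence)
  expect_length(once$values, length(v))
  # masking and reconstruction are the exact identity on clean,
  # smoothly varying data
  slow <- 5 + 0.5 * sin(2 * pi * 0.2 * t)
  m <- maskArtifacts(t, slow, rep(1, length(t)))
  expect_identical(interpolateMissing(t, m$values), slow)
  # the filter is idempotent for signals well inside the passband (a
  # Butterworth filter is not a projection, so this needs band-limited
  # input: |H|^2 at 0.2 Hz differs from 1 by ~1e-8)
  o1 <- cleanPupilSeries(t, slow, rep(1, length(t)))
  o2 <- cleanPupilSeries(t, o1$values, rep(1, length(t)))
  expect_lt(max(abs(o2$values - o1$values)) / max(abs(o1$values)), 1e-6)
})

test_that("trial extraction re-indexes to onset with the standard
           window", {
  t <- seq(0, 200, by = 1 / 120)
  v <- rep(5, length(t))
  seg <- extractTrial(t, v, onset_s = 100)
  expect_gte(min(seg@time), -5)
  expect_lte(max(seg@time), 65)
  expect_equal(range(seg@time + 100), c(95, 165), tolerance = 1 / 120)
  expect_equal(length(seg@time), 70 * 120 + 1)
  seg0 <- extractTrial(t, v, onset_s = 100, pre_s = 0)
  expect_gte(min(seg0@time), 0)
  expect_error(extractTrial(t, v, onset_s = 300), "outside")
  expect_warning(extractTrial(t, v, onset_s = 2), "truncated")
})

test_that("percent change is baseline-referenced and scale-invariant", {
  t <- seq(-5, 65, by = 1 / 120)
  const <- new("TrialSegment", time = t, values = rep(6, length(t)),
               onset = 0, units = "mm")
  expect_equal(percentChange(const)@values, rep(0, length(t)))
  v <- ifelse(t > 0 & t < 2, 3, 6)
  seg <- new("TrialSegment", time = t, values = v, onset = 0,
             units = "mm")
  pc <- percentChange(seg)
  expect_equal(min(pc@values), -50)
  scaled <- new("TrialSegment", time = t, values = 3.2 * v, onset = 0,
                units = "mm")
  expect_equal(percentChange(scaled)@values, pc@values,
               tolerance = 1e-12)
  expect_error(percentChange(new("TrialSegment", time = t,
                                 values = rep(0, length(t)), onset = 0,
                                 units = "mm")), "positive")
})
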