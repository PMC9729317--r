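#' @include engine.R preprocess.R stamper.R
NULL

#' Specification of a synthetic PLR/PIPR pupil trace
#'
#' The waveform model: flat baseline; after \code{latency_s} the pupil
#' constricts along a C1 smoothstep to \code{baseline_mm - amplitude_mm}
#' over \code{constriction_duration_s} (the smoothstep makes the peak
#' time exact); it then recovers exponentially with time constant
#' \code{recovery_tau_s} toward \code{baseline_mm - sustained_fraction *
#' amplitude_mm}. A non-zero sustained fraction models the
#' melanopsin-mediated sustained constriction seen after short-wavelength
#' stimulation. Gaussian noise and Poisson-placed blinks are added on
#' top. When \code{sustained_fraction < 0.25}, the analytic 75%-recovery
#' time is \code{recovery_tau_s * log((1 - sf) / (0.25 - sf))}
#' (\code{tau * log(4)} at sf = 0).
#'
#' Defaults echo the scale of adult PLR recordings: 5.5 mm baseline,
#' 2.7 mm constriction, 250 ms latency, 120 Hz sampling.
#'
#' @param baseline_mm prestimulus diameter (mm).
#' @param amplitude_mm constriction amplitude (< baseline).
#' @param latency_s onset-to-constriction delay (s).
#' @param constriction_duration_s latency point to peak constriction (s).
#' @param recovery_tau_s exponential recovery time constant (s).
#' @param sustained_fraction in [0, 1): persisting fraction of the
#'   constriction amplitude.
#' @param noise_sd_mm additive Gaussian noise sd.
#' @param blink_rate_hz Poisson blink rate.
#' @param sample_rate_hz sampling rate.
#' @param seed integer RNG seed.
#' @return a list of class \code{PLRSpec}.
#' @export
plrSpec <- function(baseline_mm = 5.5, amplitude_mm = 2.7,
                    latency_s = 0.25, constriction_duration_s = 0.75,
                    recovery_tau_s = 1.5, sustained_fraction = 0,
                    noise_sd_mm = 0.05, blink_rate_hz = 0.1,
                    sample_rate_hz = 120, seed = 1L) {
  spec <- list(baseline_mm = baseline_mm, amplitude_mm = amplitude_mm,
               latency_s = latency_s,
               constriction_duration_s = constriction_duration_s,
               recovery_tau_s = recovery_tau_s,
               sustained_fraction = sustained_fraction,
               noise_sd_mm = noise_sd_mm, blink_rate_hz = blink_rate_hz,
               sample_rate_hz = sample_rate_hz, seed = as.integer(seed))
  if (amplitude_mm >= baseline_mm) stop("amplitude must be below baseline")
  if (sustained_fraction < 0 || sustained_fraction >= 1) {
    stop("sustained_fraction must be in [0, 1)")
  }
  if (latency_s <= 0 || constriction_duration_s <= 0 ||
      recovery_tau_s <= 0) {
    stop("durations must be positive")
  }
  structure(spec, class = "PLRSpec")
}

# noiseless waveform of one pulse response at times t (s, onset at 0)
plrWaveform <- function(spec, t) {
  b <- spec$baseline_mm
  a <- spec$amplitude_mm
  lat <- spec$latency_s
  cd <- spec$constriction_duration_s
  tau <- spec$recovery_tau_s
  sf <- spec$sustained_fraction
  v <- rep(b, length(t))
  con <- t > lat & t <= lat + cd
  u <- (t[con] - lat) / cd
  v[con] <- b - a * (3 * u^2 - 2 * u^3)
  rec <- t > lat + cd
  v[rec] <- b - a * (sf + (1 - sf) * exp(-(t[rec] - lat - cd) / tau))
  v
}

# analytic ground truth derived from a spec
plrTruth <- function(spec) {
  sf <- spec$sustained_fraction
  t75 <- if (sf < 0.25) {
    spec$recovery_tau_s * log((1 - sf) / (0.25 - sf))
  } else {
    NA_real_
  }
  list(baseline_mm = spec$baseline_mm,
       amplitude_mm = spec$amplitude_mm,
       peak_con_mm = spec$baseline_mm - spec$amplitude_mm,
       latency_s = spec$latency_s,
       peak_time_s = spec$latency_s + spec$constriction_duration_s,
       t75_s = t75,
       sustained_percent = -100 * sf * spec$amplitude_mm /
         spec$baseline_mm)
}

#' Generate a synthetic PLR recording with ground truth
#'
#' @param spec a \code{\link{plrSpec}}.
#' @param pre_s,post_s recording extent before/after stimulus onset (s).
#' @param t0 absolute timestamp of stimulus onset (s).
#' @param eye_id eye identifier stored in the records.
#' @return list with \code{records} (data.frame: \code{pupil_timestamp},
#'   \code{eye_id}, \code{confidence}, \code{diameter} in px,
#'   \code{diameter_3d} in mm), \code{truth} (analytic parameter
#'   bundle including onset and, when defined, the 75%-recovery time),
#'   and \code{blinks} (event log).
#' @examples
#' g <- generatePlr(plrSpec(noise_sd_mm = 0, blink_rate_hz = 0))
#' min(g$records$diameter_3d)  # baseline - amplitude
#' @export
generatePlr <- function(spec, pre_s = 5, post_s = 65, t0 = 0,
                        eye_id = 0L) {
  stopifnot(inherits(spec, "PLRSpec"), pre_s > 0, post_s > 0)
  dt <- 1 / spec$sample_rate_hz
  t <- seq(-pre_s, post_s, by = dt)
  v <- plrWaveform(spec, t)
  conf <- rep(1, length(t))
  blinks <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  withLocalSeed(spec$seed, {
    if (spec$noise_sd_mm > 0) {
      v <- v + stats::rnorm(length(v), sd = spec$noise_sd_mm)
    }
    if (spec$blink_rate_hz > 0) {
      bl <- placeBlinks(t, v, conf, spec$blink_rate_hz,
                        spec$sample_rate_hz)
      v <- bl$values; conf <- bl$confidence; blinks <- bl$events
    }
  })
  records <- data.frame(
    pupil_timestamp = t0 + t,
    eye_id = as.integer(eye_id),
    confidence = conf,
    diameter = v * 40,  # nominal px scale of the eye camera
    diameter_3d = v
  )
  truth <- c(plrTruth(spec), list(onset_timestamp = t0))
  list(records = records, truth = truth, blinks = blinks)
}

# Poisson-placed blink events: linear collapse toward zero over 3
# samples, a held closure, 3-sample recovery; confidence drops to 0.2
placeBlinks <- function(t, v, conf, rate_hz, rate_sample,
                        duration_s_range = c(0.1, 0.3)) {
  dur <- max(t) - min(t)
  n <- stats::rpois(1L, rate_hz * dur)
  events <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  if (n > 0L) {
    onsets <- sort(stats::runif(n, min(t) + 0.5, max(t) - 0.5))
    lens <- stats::runif(n, duration_s_range[1L], duration_s_range[2L])
    ramp <- 3L
    for (k in seq_len(n)) {
      i0 <- which.min(abs(t - onsets[k]))
      hold <- max(1L, round(lens[k] * rate_sample))
      iEnd <- min(length(t), i0 + hold + 2L * ramp)
      idx <- i0:iEnd
      prof <- rep(0.03, length(idx))  # near-total occlusion
      down <- seq_len(min(ramp, length(idx)))
      prof[down] <- seq(1, 0.03, length.out = length(down))
      up <- seq(max(1L, length(idx) - ramp + 1L), length(idx))
      prof[up] <- pmax(prof[up], seq(0.03, 1, length.out = length(up)))
      v[idx] <- v[idx] * prof
      conf[idx] <- pmin(conf[idx], 0.2)
      events <- rbind(events, data.frame(onset_s = t[i0],
                                         duration_s = (iEnd - i0) /
                                           rate_sample))
    }
  }
  list(values = v, confidence = conf, events = events)
}

#' Inject blinks into an existing pupil series
#'
#' @param records a pupil-record \code{data.frame} (as from
#'   \code{\link{generatePlr}}).
#' @param rate_hz Poisson blink rate (0 returns the input unchanged).
#' @param duration_s_range min/max blink duration (s).
#' @param seed integer RNG seed.
#' @return list with modified \code{records} and the blink \code{events}
#'   log.
#' @export
injectBlinks <- function(records, rate_hz, duration_s_range = c(0.1, 0.3),
                         seed = 1L) {
  if (rate_hz == 0) {
    return(list(records = records,
                events = data.frame(onset_s = numeric(0),
                                    duration_s = numeric(0))))
  }
  rate_sample <- 1 / stats::median(diff(records$pupil_timestamp))
  out <- withLocalSeed(seed, {
    placeBlinks(records$pupil_timestamp, records$diameter_3d,
                records$confidence, rate_hz, rate_sample,
                duration_s_range)
  })
  records$diameter_3d <- out$values
  records$diameter <- out$values * 40
  records$confidence <- out$confidence
  list(records = records, events = out$events)
}

#' Specification of a synthetic camera frame stream
#'
#' A constant-luminance stream with one additive step, standing in for a
#' forward-facing scene camera watching a light source switch on.
#'
#' @param fps frames per second (60 or 120 are typical camera settings).
#' @param duration_s stream length (s).
#' @param baseline_mean_rgb mean frame intensity before the step (0-255).
#' @param step_frame_index 1-based frame index at which the step occurs.
#' @param step_delta intensity step height.
#' @param noise_sd per-frame Gaussian intensity noise.
#' @param seed integer RNG seed.
#' @return a list of class \code{FrameStreamSpec}.
#' @export
frameStreamSpec <- function(fps = 120, duration_s = 2,
                            baseline_mean_rgb = 80, step_frame_index = 120,
                            step_delta = 40, noise_sd = 0, seed = 1L) {
  n <- floor(fps * duration_s)
  if (step_frame_index < 2L || step_frame_index > n) {
    stop("step frame must lie within the stream (and not be the first)")
  }
  structure(list(fps = fps, duration_s = duration_s,
                 baseline_mean_rgb = baseline_mean_rgb,
                 step_frame_index = as.integer(step_frame_index),
                 step_delta = step_delta, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "FrameStreamSpec")
}

#' Generate a camera frame stream with a luminance step
#'
#' @param spec a \code{\link{frameStreamSpec}}.
#' @param t0 timestamp of the first frame (s).
#' @return list with \code{frames} (data.frame: \code{timestamp_s},
#'   \code{mean_rgb}) and \code{truth} (\code{step_timestamp_s},
#'   \code{step_frame_index}).
#' @export
generateFrames <- function(spec, t0 = 0) {
  stopifnot(inherits(spec, "FrameStreamSpec"))
  n <- floor(spec$fps * spec$duration_s)
  t <- t0 + (seq_len(n) - 1L) / spec$fps
  v <- rep(spec$baseline_mean_rgb, n)
  v[seq_len(n) >= spec$step_frame_index] <-
    spec$baseline_mean_rgb + spec$step_delta
  if (spec$noise_sd > 0) {
    v <- v + withLocalSeed(spec$seed, stats::rnorm(n, sd = spec$noise_sd))
  }
  list(frames = data.frame(timestamp_s = t, mean_rgb = v),
       truth = list(step_timestamp_s = t[spec$step_frame_index],
                    step_frame_index = spec$step_frame_index))
}

#' Generate a stream of topic-keyed sample records
#'
#' Emulates a real-time message stream mixing pupil and gaze topics, for
#' exercising timed topic capture.
#'
#' @param duration_s stream length.
#' @param rate_hz per-topic sample rate.
#' @param topics character vector of topic strings.
#' @param t0 first timestamp.
#' @param seed integer seed for the sample values.
#' @return a list of records, each with \code{topic}, \code{timestamp},
#'   \code{diameter}, \code{confidence}, ordered by timestamp.
#' @export
generateSampleStream <- function(duration_s, rate_hz = 120,
                                 topics = c("pupil.0.3d", "pupil.1.3d",
                                            "gaze.3d"),
                                 t0 = 0, seed = 1L) {
  n <- floor(duration_s * rate_hz)
  recs <- list()
  vals <- withLocalSeed(seed, stats::runif(n * length(topics), 3, 7))
  k <- 0L
  for (i in seq_len(n)) {
    for (topic in topics) {
      k <- k + 1L
      recs[[k]] <- list(topic = topic,
                        timestamp = t0 + (i - 1L) / rate_hz,
                        diameter = vals[k], confidence = 1)
    }
  }
  recs
}

#' Write a complete synthetic recording session to disk
#'
#' Emulates a sustained-response (PIPR) protocol: blue and red one-second
#' pulses in random order with jittered onsets (5-10 s after each cue)
#' and regular spacing, recorded binocularly. Emits a pupil-export CSV
#' (\code{pupil_positions.csv}), a scene-camera frame-summary CSV
#' (\code{world_frames.csv}), an annotation CSV (\code{annotations.csv})
#' whose timestamps are produced by running the light-onset detector on
#' the frame stream, and \code{ground_truth.json} with the planted
#' parameters.
#'
#' The second eye gets slightly lower confidence and more noise so that
#' eye selection has a correct answer.
#'
#' @param out_dir output directory (created if needed).
#' @param n_blue,n_red trials per condition.
#' @param spacing_s cue-to-cue spacing (default 120 s).
#' @param blue_sustained,red_sustained sustained fractions of the two
#'   conditions (defaults 0.10 and 0).
#' @param spec base \code{\link{plrSpec}} shared by all trials.
#' @param fps scene-camera frame rate.
#' @param seed master seed.
#' @return invisibly, the ground-truth list.
#' @export
writeFixtureSession <- function(out_dir, n_blue = 3, n_red = 3,
                                spacing_s = 120, blue_sustained = 0.10,
                                red_sustained = 0,
                                spec = plrSpec(), fps = 60, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  session <- simulateSession(n_blue = n_blue, n_red = n_red,
                             spacing_s = spacing_s,
                             blue_sustained = blue_sustained,
                             red_sustained = red_sustained,
                             spec = spec, fps = fps, seed = seed)
  utils::write.csv(session$records, file.path(out_dir,
                                              "pupil_positions.csv"),
                   row.names = FALSE)
  utils::write.csv(session$frames, file.path(out_dir, "world_frames.csv"),
                   row.names = FALSE)
  writeAnnotations(session$annotations$label,
                   session$annotations$timestamp,
                   file.path(out_dir, "annotations.csv"))
  jsonlite::write_json(session$truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(session$truth)
}

#' Simulate a full recording session in memory
#'
#' The in-memory engine behind \code{\link{writeFixtureSession}}; see
#' there for the protocol. Returns the raw tables plus ground truth
#' without touching disk.
#'
#' @inheritParams writeFixtureSession
#' @return list with \code{records}, \code{frames},
#'   \code{annotations} (from the light-onset detector) and
#'   \code{truth}.
#' @export
simulateSession <- function(n_blue = 3, n_red = 3, spacing_s = 120,
                            blue_sustained = 0.10, red_sustained = 0,
                            spec = plrSpec(), fps = 60, seed = 1L) {
  nTrials <- n_blue + n_red
  conditions <- withLocalSeed(seed, {
    sample(c(rep("blue", n_blue), rep("red", n_red)))
  })
  cueTimes <- 30 + (seq_len(nTrials) - 1L) * spacing_s
  jitter <- withLocalSeed(seed + 1L, stats::runif(nTrials, 5, 10))
  rawOnsets <- cueTimes + jitter
  # snap each onset to the scene-camera frame grid so the stamped frame
  # time is the true onset
  onsets <- round(rawOnsets * fps) / fps
  tEnd <- if (nTrials) max(onsets) + 70 else 60
  dt <- 1 / spec$sample_rate_hz
  t <- seq(0, tEnd, by = dt)

  # each trial contributes a constriction deficit that is tapered back
  # to zero over 70-75 s post-onset, well outside the 65 s extraction
  # window, so a sustained plateau does not leak into the next baseline
  vTrue <- rep(spec$baseline_mm, length(t))
  for (k in seq_len(nTrials)) {
    sk <- spec
    sk$sustained_fraction <- if (conditions[k] == "blue") blue_sustained
      else red_sustained
    rel <- t - onsets[k]
    act <- rel > 0 & rel < 75
    deficit <- spec$baseline_mm - plrWaveform(sk, rel[act])
    taper <- pmin(1, pmax(0, (75 - rel[act]) / 5))
    vTrue[act] <- vTrue[act] - deficit * taper
  }

  mkEye <- function(eyeId, noiseMul, confBase, subSeed) {
    v <- vTrue
    conf <- rep(confBase, length(t))
    withLocalSeed(subSeed, {
      if (spec$noise_sd_mm > 0) {
        v <- v + stats::rnorm(length(v), sd = spec$noise_sd_mm * noiseMul)
      }
      if (spec$blink_rate_hz > 0) {
        bl <- placeBlinks(t, v, conf, spec$blink_rate_hz,
                          spec$sample_rate_hz)
        v <- bl$values; conf <- bl$confidence
      }
    })
    data.frame(pupil_timestamp = t, eye_id = eyeId, confidence = conf,
               diameter = v * 40, diameter_3d = v)
  }
  records <- rbind(mkEye(0L, 1.0, 1.0, seed + 2L),
                   mkEye(1L, 1.5, 0.98, seed + 3L))
  records <- records[order(records$pupil_timestamp, records$eye_id), ]

  # scene camera: 1 s luminance pulses at the onsets
  ft <- seq(0, tEnd, by = 1 / fps)
  fv <- rep(60, length(ft))
  for (k in seq_len(nTrials)) {
    fv[ft >= onsets[k] - 1e-9 & ft < onsets[k] + 1] <- 200
  }
  frames <- data.frame(timestamp_s = ft, mean_rgb = fv)

  # light-stamp each trial from its cue onward
  stamped <- vapply(seq_len(nTrials), function(k) {
    sub <- frames[frames$timestamp_s >= cueTimes[k], , drop = FALSE]
    res <- lightStamp(sub, threshold = 10, timeout_s = 60)
    if (!res$detected) stop("session simulation failed to stamp a trial")
    res$timestamp_s
  }, numeric(1))
  annotations <- data.frame(label = conditions, timestamp = stamped)

  condSpec <- function(sf) { s <- spec; s$sustained_fraction <- sf; s }
  truth <- list(
    onsets = onsets, conditions = conditions,
    cue_times = cueTimes,
    spec = unclass(spec),
    blue = plrTruth(condSpec(blue_sustained)),
    red = plrTruth(condSpec(red_sustained)),
    sustained_difference_percent =
      plrTruth(condSpec(blue_sustained))$sustained_percent -
      plrTruth(condSpec(red_sustained))$sustained_percent
  )
  list(records = records, frames = frames, annotations = annotations,
       truth = truth)
}
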