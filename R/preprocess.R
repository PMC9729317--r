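#' @include AllClasses.R
NULL

#' Read a pupil-export table
#'
#' Expects the eye-tracker export layout: columns
#' \code{pupil_timestamp}, \code{eye_id}, \code{confidence},
#' \code{diameter} (px) and \code{diameter_3d} (mm, from the 3D eye
#' model).
#'
#' @param path CSV file path.
#' @return a \code{data.frame}.
#' @export
readPupilExport <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pupil_timestamp", "eye_id", "confidence", "diameter",
            "diameter_3d")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("pupil export is missing columns: ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Select the eye with the highest average confidence
#'
#' @param records a pupil-export \code{data.frame} (columns
#'   \code{eye_id}, \code{confidence}).
#' @return the selected eye id (0 or 1); ties go to eye 0.
#' @export
selectEye <- function(records) {
  if (!nrow(records)) stop("no pupil records")
  m <- tapply(records$confidence, records$eye_id, mean)
  eyes <- as.integer(names(m))
  best <- eyes[m == max(m)]
  min(best)  # tie -> lower eye id (eye 0)
}

#' Mask blink and low-confidence artifacts
#'
#' Samples are replaced by NA where the first time-derivative of the
#' series deviates from its mean by more than \code{sd_k} standard
#' deviations (derivative SD, computed over the whole series), or where
#' confidence falls strictly below \code{conf_min}. The derivative at
#' sample i is the time-aware backward difference
#' (value[i]-value[i-1])/(t[i]-t[i-1]), so a one-sample spike masks the
#' two samples flanking its two outlying difference values.
#'
#' @param time numeric timestamps (s), non-decreasing.
#' @param values numeric series (pupil diameter).
#' @param confidence numeric in [0, 1], same length (optional).
#' @param sd_k derivative rejection threshold in SDs (default 3).
#' @param conf_min confidence threshold; samples with confidence
#'   strictly below it are masked (default 0.95).
#' @return a list with \code{values} (masked series), and \code{report}:
#'   counts \code{by_derivative}, \code{by_confidence}, \code{by_both},
#'   \code{total}.
#' @export
maskArtifacts <- function(time, values, confidence = NULL, sd_k = 3,
                          conf_min = 0.95) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 samples")
  d <- diff(values) / diff(time)
  mu <- mean(d, na.rm = TRUE)
  sdd <- stats::sd(d, na.rm = TRUE)
  derivBad <- rep(FALSE, n)
  if (is.finite(sdd) && sdd > 0) {
    bad <- which(abs(d - mu) > sd_k * sdd)
    derivBad[bad + 1L] <- TRUE  # difference i sits at sample i+1
  }
  confBad <- rep(FALSE, n)
  if (!is.null(confidence)) confBad <- confidence < conf_min
  mask <- derivBad | confBad
  if (all(mask)) stop("all samples masked; nothing left to interpolate")
  out <- values
  out[mask] <- NA_real_
  list(values = out,
       report = list(by_derivative = sum(derivBad),
                     by_confidence = sum(confBad),
                     by_both = sum(derivBad & confBad),
                     total = sum(mask)))
}

#' Reconstruct missing samples by linear interpolation
#'
#' Interior gaps are filled linearly in time; leading and trailing gaps,
#' where linear interpolation is undefined, are filled with the nearest
#' valid value.
#'
#' @param time numeric timestamps.
#' @param values numeric series with NAs to fill.
#' @return the reconstructed series.
#' @export
interpolateMissing <- function(time, values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all samples missing")
  if (all(ok)) return(values)
  if (sum(ok) == 1L) return(rep(values[ok], length(values)))
  stats::approx(time[ok], values[ok], xout = time, method = "linear",
                rule = 2)$y
}

#' Zero-phase Butterworth low-pass smoothing
#'
#' Designs a Butterworth low-pass filter and applies it forward and
#' backward (zero phase), so no lag is introduced into latency-sensitive
#' measures. The two passes square the magnitude response: the effective
#' gain at the cutoff is |H|^2 = 0.5, and in general
#' 1 / (1 + (f/cutoff)^(2*order)).
#'
#' @param values numeric series (regularly sampled).
#' @param sample_rate_hz sampling rate; must exceed twice the cutoff.
#' @param order filter order (default 3).
#' @param cutoff_hz cutoff frequency (default 4 Hz).
#' @return the filtered series (same length, timestamps unchanged).
#' @export
lowpassFilter <- function(values, sample_rate_hz, order = 3,
                          cutoff_hz = 4) {
  if (cutoff_hz >= sample_rate_hz / 2) {
    stop("cutoff must be below the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2),
                       type = "low")
  # odd-reflection padding suppresses the forward-backward edge
  # transients; pad length covers several filter time constants
  n <- length(values)
  p <- min(n - 1L, max(12L, ceiling(6 * sample_rate_hz / cutoff_hz)))
  front <- 2 * values[1L] - values[(p + 1L):2L]
  back <- 2 * values[n] - values[(n - 1L):(n - p)]
  padded <- c(front, values, back)
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[(p + 1L):(p + n)]
}

#' Extract one trial around a stimulus onset
#'
#' Re-indexes the series to the onset timestamp and keeps
#' [-pre_s, +post_s]. Partial coverage is truncated with a warning; an
#' onset outside the series is an error.
#'
#' @param time absolute timestamps (s).
#' @param values numeric series.
#' @param onset_s stimulus onset timestamp.
#' @param pre_s,post_s window extent before/after onset (defaults 5 and
#'   65 s, the standard extraction for sustained-response protocols).
#' @param units trace units tag (\code{"mm"}, \code{"px"} or
#'   \code{"percent_change"}).
#' @return a \code{TrialSegment}.
#' @export
extractTrial <- function(time, values, onset_s, pre_s = 5, post_s = 65,
                         units = "mm") {
  if (onset_s < min(time) || onset_s > max(time)) {
    stop("onset lies outside the recorded series")
  }
  if (onset_s - pre_s < min(time) || onset_s + post_s > max(time)) {
    warning("trial window truncated to the recorded series")
  }
  keep <- time >= onset_s - pre_s & time <= onset_s + post_s
  new("TrialSegment", time = time[keep] - onset_s, values = values[keep],
      onset = onset_s, units = units)
}

#' Convert a trial to percent change from prestimulus baseline
#'
#' \code{100 * (value - baseline) / baseline}, with the baseline the
#' mean over the \code{baseline_s} seconds immediately before onset.
#'
#' @param segment a \code{TrialSegment} in mm or px.
#' @param baseline_s baseline window length (default 5 s).
#' @return a \code{TrialSegment} in \code{percent_change} units.
#' @export
percentChange <- function(segment, baseline_s = 5) {
  inBase <- segment@time >= -baseline_s & segment@time < 0
  if (!any(inBase)) stop("baseline window is empty")
  b <- mean(segment@values[inBase])
  if (!is.finite(b) || b <= 0) stop("baseline mean must be positive")
  new("TrialSegment", time = segment@time,
      values = 100 * (segment@values - b) / b,
      onset = segment@onset, units = "percent_change")
}

#' Clean one eye's pupil series end to end
#'
#' Convenience wrapper: artifact masking, linear reconstruction and
#' zero-phase Butterworth smoothing, in that order, on an
#' already-selected eye's samples.
#'
#' @param time,values,confidence as in \code{\link{maskArtifacts}}.
#' @param sample_rate_hz sampling rate for the filter; estimated from
#'   the median sampling interval when NULL.
#' @param sd_k,conf_min,order,cutoff_hz pipeline parameters.
#' @return list with \code{values} (cleaned series), \code{report} (mask
#'   report), \code{sample_rate_hz}.
#' @export
cleanPupilSeries <- function(time, values, confidence = NULL,
                             sample_rate_hz = NULL, sd_k = 3,
                             conf_min = 0.95, order = 3, cutoff_hz = 4) {
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- 1 / stats::median(diff(time))
  }
  masked <- maskArtifacts(time, values, confidence, sd_k = sd_k,
                          conf_min = conf_min)
  filled <- interpolateMissing(time, masked$values)
  smooth <- lowpassFilter(filled, sample_rate_hz, order = order,
                          cutoff_hz = cutoff_hz)
  list(values = smooth, report = masked$report,
       sample_rate_hz = sample_rate_hz)
}
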