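#' @include metrics.R synthetic.R
NULL

#' Run the standard processing pipeline on a recorded session
#'
#' Implements the canonical sustained-response pipeline: read the
#' pupil-export and annotation tables; pick the eye with the highest
#' average confidence; mask blink and low-confidence artifacts
#' (derivative beyond \code{sd_k} SD or confidence below
#' \code{conf_min}); reconstruct by linear interpolation; smooth with a
#' zero-phase Butterworth filter; extract \code{post_s} seconds of data
#' per annotated stimulus event plus a \code{pre_s}-second baseline;
#' convert to percent change from the prestimulus baseline; and
#' summarise per condition (annotation label), including the
#' blue-minus-red sustained contrast when both conditions are present.
#'
#' @param dir session directory containing \code{pupil_positions.csv}
#'   and \code{annotations.csv} (as written by
#'   \code{\link{writeFixtureSession}}, or exported from an eye
#'   tracker).
#' @param pre_s,post_s trial window (defaults 5 and 65 s).
#' @param sd_k,conf_min masking parameters.
#' @param order,cutoff_hz Butterworth parameters.
#' @param late_window_s,offset_s sustained-metric window (see
#'   \code{\link{piprSummary}}).
#' @return list with \code{eye} (selected eye id), \code{onsets}
#'   (annotation timestamps), \code{segments} (percent-change
#'   \code{TrialSegment}s grouped by condition), \code{parameters}
#'   (per-trial \code{PLRParameters} on the absolute-unit traces),
#'   \code{mask_report}, and \code{pipr} (a \code{PiprSummary}).
#' @export
processSession <- function(dir, pre_s = 5, post_s = 65, sd_k = 3,
                           conf_min = 0.95, order = 3, cutoff_hz = 4,
                           late_window_s = c(10, 30), offset_s = 1) {
  records <- readPupilExport(file.path(dir, "pupil_positions.csv"))
  annotations <- readAnnotations(file.path(dir, "annotations.csv"))
  processSessionData(records, annotations, pre_s = pre_s,
                     post_s = post_s, sd_k = sd_k, conf_min = conf_min,
                     order = order, cutoff_hz = cutoff_hz,
                     late_window_s = late_window_s, offset_s = offset_s)
}

#' @rdname processSession
#' @param records,annotations in-memory tables with the same layout as
#'   the CSV files.
#' @export
processSessionData <- function(records, annotations, pre_s = 5,
                               post_s = 65, sd_k = 3, conf_min = 0.95,
                               order = 3, cutoff_hz = 4,
                               late_window_s = c(10, 30), offset_s = 1) {
  eye <- selectEye(records)
  rec <- records[records$eye_id == eye, ]
  rec <- rec[base::order(rec$pupil_timestamp), ]  # `order` is an argument
  cleaned <- cleanPupilSeries(rec$pupil_timestamp, rec$diameter_3d,
                              rec$confidence, sd_k = sd_k,
                              conf_min = conf_min, order = order,
                              cutoff_hz = cutoff_hz)
  segsByCond <- list()
  params <- list()
  for (i in seq_len(nrow(annotations))) {
    seg <- extractTrial(rec$pupil_timestamp, cleaned$values,
                        annotations$timestamp[i], pre_s = pre_s,
                        post_s = post_s, units = "mm")
    lab <- annotations$label[i]
    segsByCond[[lab]] <- c(segsByCond[[lab]], list(percentChange(seg,
                                                   baseline_s = pre_s)))
    params[[i]] <- parametrisePLR(seg, baseline_s = pre_s)
  }
  pipr <- piprSummary(segsByCond, late_window_s = late_window_s,
                      offset_s = offset_s)
  list(eye = eye, onsets = annotations$timestamp,
       conditions = annotations$label, segments = segsByCond,
       parameters = params, mask_report = cleaned$report, pipr = pipr)
}

#' Plot a PLR trial with its parameters
#'
#' A pupillometer-style panel: the trace with baseline, peak
#' constriction, latency and 75%-recovery markers.
#'
#' @param segment a \code{TrialSegment} in absolute units.
#' @param params optional \code{PLRParameters} (computed when NULL).
#' @return the parameters, invisibly.
#' @export
plotPLR <- function(segment, params = NULL) {
  if (is.null(params)) params <- parametrisePLR(segment)
  graphics::plot(segment@time, segment@values, type = "l",
                 xlab = "time re onset (s)",
                 ylab = sprintf("pupil diameter (%s)", segment@units))
  graphics::abline(v = 0, lty = 2)
  if (!params@degenerate) {
    graphics::abline(h = params@baseline, col = "grey")
    graphics::abline(v = params@latency, col = "blue", lty = 3)
    tpk <- segment@time[which.min(segment@values)]
    graphics::points(tpk, params@peakCon, pch = 19, col = "red")
    if (!is.na(params@t75Rec)) {
      graphics::abline(v = tpk + params@t75Rec, col = "darkgreen",
                       lty = 3)
    }
  }
  invisible(params)
}
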