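#' @include AllClasses.R
NULL

#' Detect a light onset in a camera frame stream
#'
#' Two-frame differencing: the stream is scanned keeping the two most
#' recent frames, and the onset is stamped with the timestamp of the
#' first frame whose whole-frame mean intensity exceeds the previous
#' frame's by more than \code{threshold}. Only positive steps (onsets)
#' are detected unless \code{absolute = TRUE}, which also catches
#' offsets. The timeout is measured in stream time from the first frame,
#' so detection is fully deterministic.
#'
#' @param frames a \code{data.frame} with columns \code{timestamp_s}
#'   (strictly increasing) and \code{mean_rgb} (whole-frame mean
#'   intensity, 0-255). A full pixel array per frame may be supplied as a
#'   list column \code{pixels} instead of \code{mean_rgb}; it is reduced
#'   to the mean at ingestion (the detector uses no spatial structure).
#' @param threshold positive detection threshold on the frame-to-frame
#'   difference.
#' @param timeout_s give up after this much stream time.
#' @param absolute detect steps of either sign.
#' @return object of class \code{StampResult}: list with
#'   \code{detected}, \code{timestamp_s} (NA when not detected),
#'   \code{frames_seen}, \code{threshold}.
#' @examples
#' fr <- data.frame(timestamp_s = (0:9) / 60,
#'                  mean_rgb = c(rep(10, 5), rep(50, 5)))
#' lightStamp(fr, threshold = 10)
#' @export
lightStamp <- function(frames, threshold, timeout_s = Inf,
                       absolute = FALSE) {
  if (threshold <= 0) stop("threshold must be positive")
  if (timeout_s <= 0) stop("timeout_s must be positive")
  if (!nrow(frames)) {
    return(structure(list(detected = FALSE, timestamp_s = NA_real_,
                          frames_seen = 0L, threshold = threshold),
                     class = "StampResult"))
  }
  mean_rgb <- if ("mean_rgb" %in% names(frames)) frames$mean_rgb else
    vapply(frames$pixels, function(p) mean(as.numeric(p)), numeric(1))
  t <- frames$timestamp_s
  if (any(diff(t) <= 0)) stop("frame timestamps must be strictly increasing")
  inWindow <- t <= t[1L] + timeout_s
  d <- diff(mean_rgb)
  if (absolute) d <- abs(d)
  hit <- which(d > threshold & inWindow[-1L])
  if (length(hit)) {
    i <- hit[1L] + 1L  # the first frame after the jump
    structure(list(detected = TRUE, timestamp_s = t[i],
                   frames_seen = i, threshold = threshold),
              class = "StampResult")
  } else {
    structure(list(detected = FALSE, timestamp_s = NA_real_,
                   frames_seen = sum(inWindow), threshold = threshold),
              class = "StampResult")
  }
}

#' @export
print.StampResult <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("light stamped at %.6f s (threshold %g, %d frames seen)\n",
                x$timestamp_s, x$threshold, x$frames_seen))
  } else {
    cat(sprintf("no onset detected (threshold %g, %d frames seen)\n",
                x$threshold, x$frames_seen))
  }
  invisible(x)
}

#' Apply a constant camera timestamp offset
#'
#' Camera timestamps can lead or lag the true frame exposure by a
#' platform-dependent constant (tens of milliseconds, depending on
#' operating system and frame rate). This correction is modelled as a
#' single configurable offset subtracted from the stamped time; the
#' default of 0 leaves timestamps untouched.
#'
#' @param t timestamp(s) in seconds.
#' @param offset_ms offset in milliseconds to subtract.
#' @return corrected timestamp(s) in seconds.
#' @examples
#' applyTimestampOffset(0.301, 59)  # 0.242
#' @export
applyTimestampOffset <- function(t, offset_ms = 0) {
  t - offset_ms / 1000
}

#' Capture a timed window of streamed, topic-keyed samples
#'
#' Collects every record whose topic starts with \code{topic_prefix}
#' over \code{duration_s} of stream time (measured from the first record
#' in the stream, matched or not).
#'
#' @param stream a list of records; each record is a list with fields
#'   \code{topic}, \code{timestamp} and arbitrary further data fields.
#' @param topic_prefix e.g. \code{"pupil."} for all pupil data or
#'   \code{"pupil.1.3d"} for left-eye 3D-model data only.
#' @param duration_s positive capture duration.
#' @return object of class \code{CaptureWindow}: list with
#'   \code{topic_prefix}, \code{duration_s}, \code{samples} (list of
#'   matched records).
#' @export
grabSamples <- function(stream, topic_prefix, duration_s) {
  if (duration_s <= 0) stop("duration_s must be positive")
  samples <- list()
  if (length(stream)) {
    t0 <- stream[[1L]]$timestamp
    samples <- Filter(function(r) {
      startsWith(r$topic, topic_prefix) &&
        r$timestamp >= t0 && r$timestamp <= t0 + duration_s
    }, stream)
  }
  structure(list(topic_prefix = topic_prefix, duration_s = duration_s,
                 samples = samples),
            class = "CaptureWindow")
}

#' @export
print.CaptureWindow <- function(x, ...) {
  cat(sprintf("CaptureWindow '%s': %d samples over %g s\n",
              x$topic_prefix, length(x$samples), x$duration_s))
  invisible(x)
}

#' Unpack a capture window into a columnar table
#'
#' One row per record, ordered by timestamp, with one column per data
#' key (union over records; missing entries are NA).
#'
#' @param window a \code{CaptureWindow}.
#' @return a \code{data.frame}; empty (0 rows) for an empty window.
#' @export
unpackWindow <- function(window) {
  recs <- window$samples
  if (!length(recs)) return(data.frame())
  keys <- setdiff(unique(unlist(lapply(recs, names))), "topic")
  cols <- lapply(keys, function(k) {
    vapply(recs, function(r) {
      v <- r[[k]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  })
  names(cols) <- keys
  # topic is textual; recover it separately
  cols$topic <- vapply(recs, function(r) as.character(r$topic),
                       character(1))
  df <- as.data.frame(cols[!duplicated(names(cols))],
                      stringsAsFactors = FALSE)
  df[order(df$timestamp), , drop = FALSE]
}

#' Read and write annotation tables
#'
#' Two-column CSV (\code{label}, \code{timestamp}) compatible with the
#' trial-extraction step.
#'
#' @param labels character vector of event labels.
#' @param timestamps numeric vector of event times (s).
#' @param path file path.
#' @return \code{readAnnotations} returns a \code{data.frame} with
#'   columns \code{label} and \code{timestamp}.
#' @export
writeAnnotations <- function(labels, timestamps, path) {
  utils::write.csv(data.frame(label = labels, timestamp = timestamps),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
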