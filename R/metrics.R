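#' @include preprocess.R
NULL

#' Velocity and acceleration of a trial by central differences
#'
#' First and second time derivatives of the trace; endpoints use
#' one-sided differences. Exact for quadratics on a uniform grid.
#'
#' @param segment a \code{TrialSegment} (near-uniform sampling).
#' @return list with \code{time}, \code{velocity}, \code{acceleration}.
#' @export
trialDerivatives <- function(segment) {
  t <- segment@time
  x <- segment@values
  if (length(t) < 5L) stop("need at least 5 samples for derivatives")
  v <- centralDiff(t, x)
  a <- centralDiff(t, v)
  list(time = t, velocity = v, acceleration = a)
}

centralDiff <- function(t, x) {
  n <- length(x)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (x[i + 1L] - x[i - 1L]) / (t[i + 1L] - t[i - 1L])
  d
}

#' Pupillometer-style parametrisation of one PLR trial
#'
#' Computes, on a baseline-and-onset-indexed trial in absolute units:
#' \itemize{
#'   \item \code{baseline}: mean diameter over the prestimulus window;
#'   \item \code{peakCon}: the post-onset minimum diameter;
#'   \item \code{latency}: time from onset to the negative acceleration
#'     peak of the initial constriction (acceleration minimum restricted
#'     to the interval from onset to peak constriction);
#'   \item \code{vconAve}: (peakCon - baseline) / (t_peak - latency),
#'     signed negative;
#'   \item \code{vconMax}: minimum velocity between latency and peak;
#'   \item \code{vredAve}: mean velocity from peak constriction to the
#'     75\%-recovery time (or the window end when 75\% is never
#'     reached), signed positive during redilation;
#'   \item \code{t75Rec}: time after peak constriction at which the
#'     diameter first recovers 75\% of the constriction amplitude, i.e.
#'     crosses peak + 0.75 * (baseline - peak); NA when the trace
#'     plateaus below that level through the window end.
#' }
#' A trial with no constriction (post-onset minimum at or above
#' baseline) is flagged degenerate and all parameters are NA.
#'
#' The 75\% criterion is interpreted as recovery of 75\% of the
#' constriction amplitude; \code{recovery_fraction} makes the threshold
#' configurable. \code{upsample_factor} > 1 cubically upsamples the trace
#' before derivative estimation, which can refine latency beyond the
#' frame interval; it is off (1) by default.
#'
#' @param segment a \code{TrialSegment} in mm or px, onset at time 0.
#' @param baseline_s prestimulus baseline window length (s).
#' @param recovery_fraction recovered fraction of the constriction
#'   amplitude defining T75-style recovery (default 0.75).
#' @param upsample_factor integer >= 1; cubic-spline upsampling factor
#'   applied before derivative-based measures.
#' @return a \code{PLRParameters}.
#' @export
parametrisePLR <- function(segment, baseline_s = 5,
                           recovery_fraction = 0.75,
                           upsample_factor = 1) {
  if (segment@units == "percent_change") {
    stop("parametrise absolute-unit traces (mm or px), not percent change")
  }
  t <- segment@time
  x <- segment@values
  if (upsample_factor > 1) {
    tt <- seq(min(t), max(t), length.out = upsample_factor * length(t))
    x <- stats::spline(t, x, xout = tt)$y
    t <- tt
  }
  inBase <- t >= -baseline_s & t < 0
  if (!any(inBase) || !any(t > 0)) {
    stop("segment must cover the baseline window and the post-onset period")
  }
  baseline <- mean(x[inBase])
  post <- which(t > 0)
  ipk <- post[which.min(x[post])]
  peak <- x[ipk]
  tpk <- t[ipk]
  na <- function() new("PLRParameters", baseline = baseline,
                       peakCon = NA_real_, latency = NA_real_,
                       vconAve = NA_real_, vconMax = NA_real_,
                       vredAve = NA_real_, t75Rec = NA_real_,
                       accPeakTime = NA_real_, degenerate = TRUE)
  if (peak >= baseline) return(na())
  seg <- new("TrialSegment", time = t, values = x, onset = segment@onset,
             units = segment@units)
  der <- trialDerivatives(seg)
  # latency: negative acceleration peak within (0, t_peak]
  win <- which(t > 0 & t <= tpk)
  if (!length(win)) return(na())
  iacc <- win[which.min(der$acceleration[win])]
  latency <- t[iacc]
  conWin <- which(t > latency & t <= tpk)
  vconMax <- if (length(conWin)) min(der$velocity[conWin]) else NA_real_
  vconAve <- if (tpk > latency) (peak - baseline) / (tpk - latency) else
    NA_real_
  # recovery: first crossing of the recovered-amplitude threshold
  thr <- peak + recovery_fraction * (baseline - peak)
  rec <- which(t > tpk & x >= thr)
  t75 <- if (length(rec)) t[rec[1L]] - tpk else NA_real_
  redEnd <- if (length(rec)) rec[1L] else length(t)
  redWin <- ipk:redEnd
  vredAve <- mean(der$velocity[redWin])
  new("PLRParameters", baseline = baseline, peakCon = peak,
      latency = latency, vconAve = vconAve, vconMax = vconMax,
      vredAve = vredAve, t75Rec = t75, accPeakTime = latency,
      degenerate = FALSE)
}

#' Summarise PLR parameters over trials
#'
#' Per-parameter mean and standard deviation over defined (non-NA)
#' values only; trials where a parameter is undefined are excluded from
#' that parameter's average and counted instead. SD is reported as 0
#' when only one defined value remains.
#'
#' @param trials a list of \code{PLRParameters}.
#' @return object of class \code{SessionSummary}: list with
#'   \code{table} (data.frame: parameter, mean, sd, n, n_undefined) and
#'   \code{n_trials}.
#' @export
summariseTrials <- function(trials) {
  if (!length(trials)) stop("need at least one trial")
  df <- do.call(rbind, lapply(trials, as.data.frame))
  stats_ <- lapply(names(df), function(p) {
    v <- df[[p]]
    ok <- !is.na(v)
    data.frame(parameter = p,
               mean = if (any(ok)) mean(v[ok]) else NA_real_,
               sd = if (sum(ok) > 1L) stats::sd(v[ok]) else
                 if (sum(ok) == 1L) 0 else NA_real_,
               n = sum(ok), n_undefined = sum(!ok))
  })
  structure(list(table = do.call(rbind, stats_), n_trials = nrow(df)),
            class = "SessionSummary")
}

#' @export
print.SessionSummary <- function(x, ...) {
  cat(sprintf("Session summary over %d trials:\n", x$n_trials))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Post-illumination pupil response summary by condition
#'
#' Pointwise mean percent-change trace per condition (segments regridded
#' onto the first segment's time base when they differ) and a sustained
#' constriction metric: the mean percent change over a late window
#' after stimulus offset. When conditions named \code{"blue"} and
#' \code{"red"} are both present, their sustained difference
#' (blue minus red) is reported -- the melanopsin-mediated contrast.
#'
#' @param segments named list of conditions, each a list of
#'   percent-change \code{TrialSegment}s.
#' @param late_window_s numeric(2), window for the sustained metric in
#'   seconds after stimulus offset (default c(10, 30)).
#' @param offset_s stimulus offset time relative to onset (default 1 s,
#'   a one-second pulse).
#' @return object of class \code{PiprSummary}: list with per-condition
#'   \code{time}, \code{mean} trace, \code{sustained} metric and
#'   \code{n}; plus \code{blue_minus_red} when applicable.
#' @export
piprSummary <- function(segments, late_window_s = c(10, 30),
                        offset_s = 1) {
  stopifnot(length(segments) >= 1L, !is.null(names(segments)))
  conditions <- lapply(segments, function(trials) {
    stopifnot(length(trials) >= 1L)
    tbase <- trials[[1L]]@time
    mat <- vapply(trials, function(s) {
      if (isTRUE(all.equal(s@time, tbase))) s@values else
        stats::approx(s@time, s@values, xout = tbase, rule = 2)$y
    }, numeric(length(tbase)))
    mean_trace <- rowMeans(mat)
    late <- tbase >= offset_s + late_window_s[1L] &
            tbase <= offset_s + late_window_s[2L]
    list(time = tbase, mean = mean_trace,
         sustained = mean(mean_trace[late]), n = length(trials))
  })
  out <- list(conditions = conditions)
  if (all(c("blue", "red") %in% names(conditions))) {
    out$blue_minus_red <- conditions$blue$sustained -
      conditions$red$sustained
  }
  structure(out, class = "PiprSummary")
}

#' @export
print.PiprSummary <- function(x, ...) {
  cat("PIPR summary:\n")
  for (nm in names(x$conditions)) {
    c_ <- x$conditions[[nm]]
    cat(sprintf("  %s: n = %d, sustained = %.2f%%\n", nm, c_$n,
                c_$sustained))
  }
  if (!is.null(x$blue_minus_red)) {
    cat(sprintf("  blue - red sustained difference: %.2f%%\n",
                x$blue_minus_red))
  }
  invisible(x)
}

#' Write per-trial PLR parameters as CSV
#'
#' Column names mirror the pupillometer convention (Baseline, PeakCon,
#' Latency, VConAve, VConMax, VRedAve, T75Rec).
#'
#' @param trials a list of \code{PLRParameters}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeParametersCsv <- function(trials, path) {
  df <- do.call(rbind, lapply(trials, as.data.frame))
  df <- cbind(trial = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
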