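#' @include calibration.R
NULL

#' Per-unit-setting alpha-opic contribution matrix
#'
#' Column j is the alpha-opic irradiance vector of LED channel j at
#' maximum drive divided by 4095 -- the channel's contribution per unit
#' 12-bit setting under the linearity assumption.
#'
#' @param ctx a \code{CalibrationContext}.
#' @return a 5 x 10 matrix (rows: alpha-opic channels in canonical
#'   order).
#' @export
aopicMatrix <- function(ctx) {
  A <- vapply(0:9, function(led) contextAopic(ctx, led, 4095L) / 4095,
              numeric(5))
  rownames(A) <- aopicNames()
  A
}

# active-set bounded least squares: min ||A s - b||^2, lo <= s <= hi.
# Variables at a bound are fixed; the free subproblem is solved exactly;
# iterate until no violations and KKT multipliers are non-negative.
boundedLsq <- function(A, b, lo, hi, maxit = 200L) {
  n <- ncol(A)
  s <- rep(0, n)
  atBound <- rep(NA_character_, n)  # NA = free, "lo"/"hi" = clamped
  for (it in seq_len(maxit)) {
    free <- which(is.na(atBound))
    r0 <- b - A %*% ifelse(is.na(atBound), 0,
                           ifelse(atBound == "lo", lo, hi))
    if (length(free)) {
      # minimal-norm least squares of the free subproblem via SVD
      # (normal equations with a ridge would bias the residual)
      Af <- A[, free, drop = FALSE]
      sv <- svd(Af)
      keep <- sv$d > max(dim(Af)) * .Machine$double.eps * max(sv$d, 0)
      sol <- if (any(keep)) {
        sv$v[, keep, drop = FALSE] %*%
          ((crossprod(sv$u[, keep, drop = FALSE], r0)) / sv$d[keep])
      } else {
        rep(0, length(free))
      }
      s[free] <- as.vector(sol)
    }
    s[!is.na(atBound)] <- ifelse(atBound[!is.na(atBound)] == "lo",
                                 lo[!is.na(atBound)],
                                 hi[!is.na(atBound)])
    viol <- is.na(atBound) & (s < lo | s > hi)
    if (any(viol)) {
      atBound[viol & s < lo] <- "lo"
      atBound[viol & s > hi] <- "hi"
      next
    }
    # KKT check: gradient at clamped variables must point outward
    g <- as.vector(crossprod(A, A %*% s - b))
    release <- (!is.na(atBound) & atBound == "lo" & g < -1e-12) |
               (!is.na(atBound) & atBound == "hi" & g > 1e-12)
    if (!any(release)) break
    atBound[release] <- NA_character_
  }
  pmin(pmax(s, lo), hi)
}

# assemble a MatchResult from continuous settings
finishMatch <- function(ctx, target, sCont, method, converged = TRUE) {
  settings <- deviceSettings(round(pmin(pmax(sCont, 0), 4095)))
  achieved <- aopicIrradiance(predictSpd(ctx, settings))
  structure(list(
    settings = settings,
    achieved = achieved,
    target = target,
    residual = sum((achieved - target)^2),
    method = method,
    converged = converged
  ), class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult (%s): residual %.4g\n", x$method, x$residual))
  cat("  settings:", paste(intensities(x$settings), collapse = " "), "\n")
  df <- data.frame(target = x$target, achieved = x$achieved)
  print(round(df, 6))
  invisible(x)
}

#' Match a target alpha-opic vector by bounded linear least squares
#'
#' Solves \code{min ||A s - target||^2} subject to \code{0 <= s <= 4095}
#' with an active-set bounded least-squares solver, then rounds to
#' integer settings. The reported residual is recomputed after rounding
#' from the full calibrated forward model. A target that cannot be
#' reached within the gamut produces a best-effort result with a
#' warning.
#'
#' @param ctx a \code{CalibrationContext}.
#' @param target named or unnamed numeric(5) of non-negative alpha-opic
#'   irradiances, or a \code{Spectrum} (reduced internally).
#' @return a \code{MatchResult}: list with \code{settings},
#'   \code{achieved}, \code{target}, \code{residual}, \code{method}.
#' @export
matchLinear <- function(ctx, target) {
  target <- asAopicTarget(target)
  A <- aopicMatrix(ctx)
  s <- boundedLsq(A, target, lo = rep(0, 10), hi = rep(4095, 10))
  contResid <- sqrt(sum((A %*% s - target)^2))
  if (contResid > 1e-4 * max(sqrt(sum(target^2)), .Machine$double.eps)) {
    warning("target outside gamut: best-effort match returned")
  }
  finishMatch(ctx, target, s, "linear")
}

#' Match a target alpha-opic vector by constrained local optimisation
#'
#' Gradient-based local minimisation (L-BFGS-B with analytic gradient) of
#' the summed squared alpha-opic differences over continuous settings in
#' [0, 4095]^10, then rounding. With no explicit start, the bounded
#' linear solution is used.
#'
#' @param ctx a \code{CalibrationContext}.
#' @param target as in \code{\link{matchLinear}}.
#' @param start a \code{DeviceSettings} to start from (default: the
#'   linear solution).
#' @return a \code{MatchResult}.
#' @export
matchLocal <- function(ctx, target, start = NULL) {
  target <- asAopicTarget(target)
  A <- aopicMatrix(ctx)
  s0 <- if (is.null(start)) {
    boundedLsq(A, target, rep(0, 10), rep(4095, 10))
  } else {
    as.numeric(intensities(start))
  }
  obj <- function(s) sum((A %*% s - target)^2)
  grad <- function(s) as.vector(2 * crossprod(A, A %*% s - target))
  fit <- stats::optim(s0, obj, grad, method = "L-BFGS-B",
                      lower = rep(0, 10), upper = rep(4095, 10),
                      control = list(maxit = 1000, factr = 1))
  s <- if (fit$value <= obj(s0)) fit$par else s0  # descent guarantee
  finishMatch(ctx, target, s, "local", converged = fit$convergence == 0)
}

# accept a Spectrum or a 5-vector as the matching target
asAopicTarget <- function(target) {
  if (is(target, "Spectrum")) target <- aopicIrradiance(target)
  target <- as.numeric(target)
  if (length(target) != 5L) stop("target must have 5 alpha-opic values")
  if (any(target < 0)) stop("target alpha-opic values must be non-negative")
  names(target) <- aopicNames()
  target
}

#' Scale a stimulus in the linearised output domain
#'
#' Applies the fitted per-channel curves forward (setting to relative
#' output), multiplies by \code{factor}, clips to [0, 1] and inverts.
#' With no curves supplied the channels are taken as linear, so scaling
#' reduces to \code{round(factor * s)} within clipping.
#'
#' @param settings a \code{DeviceSettings}.
#' @param factor positive scale factor.
#' @param curves optional \code{data.frame} from \code{\link{fitCurves}}.
#' @return a \code{DeviceSettings}; warns when any channel saturates.
#' @examples
#' scaleStimulus(deviceSettings(rep(1000, 10)), 1.5)
#' @export
scaleStimulus <- function(settings, factor, curves = NULL) {
  if (factor <= 0) stop("factor must be positive")
  s <- intensities(settings)
  if (is.null(curves)) {
    alpha <- rep(1, 10); beta <- rep(1, 10)
  } else {
    alpha <- curves$alpha; beta <- curves$beta
  }
  rel <- stats::pbeta(s / 4095, alpha, beta) * factor
  if (any(rel > 1 + 1e-12)) {
    warning("stimulus scaling saturated one or more channels")
  }
  rel <- pmin(pmax(rel, 0), 1)
  deviceSettings(round(4095 * stats::qbeta(rel, alpha, beta)))
}

#' Serialise a match result to JSON
#'
#' @param x a \code{MatchResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMatchJson <- function(x, path) {
  obj <- list(settings = intensities(x$settings),
              achieved = as.list(x$achieved),
              target = as.list(x$target),
              residual = x$residual, method = x$method)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
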