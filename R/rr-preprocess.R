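#' Detect beat artifacts with a percentage-threshold median filter
#'
#' Flags beat `i` when its interval deviates from the median of the
#' surrounding window by more than `threshold_fraction` (relative to that
#' median). The centre beat is excluded from its own window median so a
#' large artifact cannot mask itself; windows are truncated at the edges.
#'
#' @param rr an [rr_series()].
#' @param window_beats odd window length in beats (centre + neighbours);
#'   default 11, i.e., 5 beats each side.
#' @param threshold_fraction relative deviation threshold; default 0.05 (5%).
#' @return An object of class `artifact_mask`: list with `flags` (logical,
#'   one per beat), `local_median`, `window_beats`, `threshold_fraction`.
#' @examples
#' s <- rr_series(c(rep(800, 20), 1600, rep(800, 20)))
#' which(detect_artifacts(s)$flags) # beat 21
#' @export
detect_artifacts <- function(rr, window_beats = 11, threshold_fraction = 0.05) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$rr)
  if (n < 3) stop("series shorter than 3 beats")
  if (window_beats %% 2 != 1 || window_beats < 3) stop("window_beats must be odd and >= 3")
  if (n < window_beats) stop("series length must be >= window_beats")
  if (threshold_fraction <= 0 || threshold_fraction >= 1) stop("threshold_fraction must be in (0, 1)")
  h <- (window_beats - 1L) %/% 2L
  med <- .windowed_median_excl(rr$rr, h)
  flags <- abs(rr$rr - med) / med > threshold_fraction
  structure(list(flags = flags, local_median = med,
                 window_beats = window_beats,
                 threshold_fraction = threshold_fraction),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d/%d beats flagged (window %d, threshold %.1f%%)\n",
              sum(x$flags), length(x$flags), x$window_beats,
              100 * x$threshold_fraction))
  invisible(x)
}

# interpolate flagged rr values over unflagged neighbours on the beat-time
# axis; fun is approx() or a spline evaluator
.interp_correct <- function(rr, flags, method) {
  xs <- rr$t[!flags]
  ys <- rr$rr[!flags]
  xt <- rr$t[flags]
  out <- rr$rr
  if (flags[1] || flags[length(flags)]) {
    message("flagged beats at series extremes: using nearest-value extrapolation")
  }
  if (method == "linear") {
    out[flags] <- approx(xs, ys, xout = xt, rule = 2)$y
  } else {
    f <- splinefun(xs, ys, method = "natural")
    v <- f(xt)
    # clamp beyond-range evaluations to nearest observed value
    v[xt < xs[1]] <- ys[1]
    v[xt > xs[length(xs)]] <- ys[length(ys)]
    out[flags] <- v
  }
  out
}

# forecast each maximal flagged run from an ARIMA fit on the preceding
# unflagged beats; fall back to linear interpolation when the preceding run
# is short or the fit fails
.arima_correct <- function(rr, flags, order, min_fit, max_fit = 120L) {
  out <- .interp_correct(rr, flags, "linear") # fallback values
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    prev <- which(!flags[seq_len(i0 - 1L)])
    if (length(prev) < min_fit) next # linear fallback already in place
    idx <- tail(prev, max_fit)
    fit <- tryCatch(
      suppressWarnings(arima(rr$rr[idx], order = order, method = "CSS")),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("ARIMA fit failed for flagged run at beat ", i0,
              "; falling back to linear interpolation")
      next
    }
    pr <- tryCatch(suppressWarnings(predict(fit, n.ahead = i1 - i0 + 1L)$pred),
                   error = function(e) NULL)
    if (is.null(pr) || any(!is.finite(pr)) || any(pr <= 0)) next
    out[i0:i1] <- as.numeric(pr)
  }
  out
}

#' Correct flagged beats in an RR series
#'
#' Applies one of the supported artifact-correction strategies to the beats
#' flagged by [detect_artifacts()]. Consecutive flagged beats are corrected
#' jointly: interpolation spans the whole gap, and ARIMA forecasts the whole
#' run from the model fitted to the preceding unflagged beats.
#'
#' Methods:
#' \describe{
#'   \item{none}{return the series unchanged (provenance updated).}
#'   \item{deletion}{remove flagged beats; survivor beat times are recomputed
#'     from the cumulative interval sum, so total duration shrinks.}
#'   \item{linear, cubic}{replace flagged interval values by linear or
#'     natural-cubic-spline interpolation of RR against beat time over the
#'     unflagged beats. Beat timestamps are kept (beats still occurred when
#'     they occurred); only interval values change.}
#'   \item{arima}{replace each flagged run by forecasts from an ARIMA model
#'     (default order (1,1,1), conditional-sum-of-squares fit) fitted on the
#'     most recent `min_fit` (default 60) or more preceding unflagged beats,
#'     falling back to linear interpolation when the preceding run is too
#'     short or the fit fails.}
#' }
#'
#' @param rr an [rr_series()].
#' @param mask an `artifact_mask` aligned to `rr`.
#' @param method one of `"none"`, `"deletion"`, `"linear"`, `"cubic"`,
#'   `"arima"`.
#' @param arima_order ARIMA (p, d, q) order; default `c(1, 1, 1)`.
#' @param min_fit minimum preceding unflagged beats for an ARIMA fit.
#' @return A corrected [rr_series()] with provenance `"corrected:<method>"`.
#'   Output length equals input length for every method except deletion.
#' @examples
#' s <- rr_series(c(rep(800, 20), 1600, rep(800, 20)))
#' m <- detect_artifacts(s)
#' round(apply_correction(s, m, "linear")$rr[21])
#' @export
apply_correction <- function(rr, mask,
                             method = c("none", "deletion", "linear", "cubic", "arima"),
                             arima_order = c(1, 1, 1), min_fit = 60L) {
  method <- match.arg(method)
  stopifnot(inherits(rr, "rr_series"), inherits(mask, "artifact_mask"))
  flags <- mask$flags
  n <- length(rr$rr)
  if (length(flags) != n) stop("mask not aligned to series")
  prov <- paste0("corrected:", method)
  if (method == "none" || !any(flags)) {
    return(rr_series(rr$rr, t = rr$t, provenance = prov))
  }
  if (all(flags)) stop("all beats flagged; cannot correct")
  if (mean(flags) >= 0.5) stop("more than half of the beats flagged; refusing to correct")
  if (method == "deletion") {
    kept <- rr$rr[!flags]
    t0 <- rr$t[1] - rr$rr[1]
    return(rr_series(kept, t0 = t0, provenance = prov))
  }
  new_rr <- switch(method,
    linear = .interp_correct(rr, flags, "linear"),
    cubic  = .interp_correct(rr, flags, "cubic"),
    arima  = .arima_correct(rr, flags, as.integer(arima_order), as.integer(min_fit)))
  rr_series(new_rr, t = rr$t, provenance = prov)
}
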