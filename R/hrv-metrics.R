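#' Extract the beats inside an analysis window
#'
#' Returns the beats whose occurrence time lies in
#' `[t_start, t_start + duration)` seconds from the start of the recording.
#' A message is emitted when the window contains less than 90 s of data,
#' below which ultra-short-term LF estimates are considered unreliable.
#'
#' @param rr an [rr_series()].
#' @param t_start window start in seconds (typically the stop time).
#' @param duration window length in seconds; default 300 (5 min).
#' @return An [rr_series()] restricted to the window.
#' @export
extract_window <- function(rr, t_start, duration = 300) {
  stopifnot(inherits(rr, "rr_series"))
  if (duration <= 0) stop("duration must be positive")
  lo <- t_start * 1000
  hi <- (t_start + duration) * 1000
  keep <- rr$t >= lo & rr$t < hi
  if (!any(keep)) stop("analysis window contains no beats")
  span <- diff(range(rr$t[keep])) / 1000
  if (span < 90) message(sprintf("window holds only %.0f s of data (< 90 s): LF estimate may be unreliable", span))
  rr_series(rr$rr[keep], t = rr$t[keep], provenance = rr$provenance)
}

#' Root mean square of successive differences (RMSSD)
#'
#' @param rr an [rr_series()] or numeric vector of RR intervals (ms).
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(800, 810, 800, 810)) # 10
#' @export
rmssd <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 2) stop("RMSSD needs at least 2 beats")
  sqrt(mean(diff(x)^2))
}

#' Standard deviation of normal-normal intervals (SDNN)
#'
#' Sample standard deviation (n - 1 denominator) of the RR intervals.
#'
#' @inheritParams rmssd
#' @return SDNN in ms.
#' @export
sdnn <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 2) stop("SDNN needs at least 2 beats")
  sd(x)
}

#' Evenly resample a tachogram by cubic-spline interpolation
#'
#' Interpolates RR against beat time with a natural cubic spline and
#' evaluates it on a uniform grid at `resample_hz`, spanning from the first
#' to the last beat (no extrapolation).
#'
#' @param rr an [rr_series()] with at least 4 beats.
#' @param resample_hz sampling rate of the output grid in Hz; default 4.
#' @return List with `t` (s), `rr` (ms) and `fs` (Hz).
#' @export
resample_tachogram <- function(rr, resample_hz = 4) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$rr) < 4) stop("resampling needs at least 4 beats")
  ts <- rr$t / 1000
  if (any(diff(ts) <= 0)) stop("duplicate or non-increasing beat times")
  f <- splinefun(ts, rr$rr, method = "natural")
  grid <- seq(ts[1], ts[length(ts)], by = 1 / resample_hz)
  list(t = grid, rr = f(grid), fs = resample_hz)
}

#' Frequency-band powers of a resampled tachogram
#'
#' Removes the mean and linear trend, computes the periodogram via the FFT
#' (no taper), and sums ordinates into the conventional HRV bands:
#' VLF (0, 0.04], LF (0.04, 0.15], HF (0.15, 0.4] Hz. Band edges are
#' lower-exclusive and upper-inclusive so no bin is counted twice; the zero
#' bin is excluded (detrending removes DC). Powers are in ms^2 and scaled so
#' that the full one-sided periodogram sums to the variance of the detrended
#' series.
#'
#' @param resampled list as returned by [resample_tachogram()] (elements
#'   `rr` and `fs`), or a numeric vector with `fs` given separately.
#' @param fs sampling rate in Hz when `resampled` is a plain vector.
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @return Named numeric vector `vlf`, `lf`, `hf`, `tp` (ms^2), with the
#'   detrended-series variance as attribute `"variance"`.
#' @export
spectral_band_powers <- function(resampled, fs = NULL,
                                 bands = list(vlf = c(0, 0.04),
                                              lf = c(0.04, 0.15),
                                              hf = c(0.15, 0.4))) {
  if (is.list(resampled)) {
    x <- resampled$rr
    fs <- resampled$fs
  } else {
    x <- as.numeric(resampled)
    if (is.null(fs)) stop("fs required for a plain vector")
  }
  n <- length(x)
  if (n < 2 * fs * 30) stop("series too short for band-power estimation (need >= 60 s)")
  tt <- seq_len(n)
  x <- residuals(lm(x ~ tt))
  v <- sum(x^2) / n
  P <- Mod(fft(x))^2 / n^2
  freq <- (seq_len(n) - 1) * fs / n
  # one-sided: positive frequencies up to Nyquist, doubled (Nyquist bin,
  # present only for even n, is not doubled)
  half <- seq(2L, floor(n / 2) + 1L)
  p <- 2 * P[half]
  if (n %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  fr <- freq[half]
  pow <- vapply(bands, function(b) sum(p[fr > b[1] & fr <= b[2]]), numeric(1))
  out <- c(pow, tp = sum(pow))
  attr(out, "variance") <- v
  out
}

#' Time- and frequency-domain HRV over an analysis window
#'
#' Convenience wrapper: extracts the window, computes RMSSD/SDNN on the
#' beat series, and VLF/LF/HF/TP on the spline-resampled tachogram.
#'
#' @inheritParams extract_window
#' @param resample_hz resampling rate for the spectral estimate (Hz).
#' @return List of class `hrv_result`: `rmssd`, `sdnn` (ms), `vlf`, `lf`,
#'   `hf`, `tp` (ms^2), `n_beats`, `resample_hz`, `correction_method`.
#' @export
hrv_window <- function(rr, t_start, duration = 300, resample_hz = 4) {
  w <- extract_window(rr, t_start, duration)
  rs <- resample_tachogram(w, resample_hz)
  bp <- spectral_band_powers(rs)
  structure(list(rmssd = rmssd(w), sdnn = sdnn(w),
                 vlf = unname(bp["vlf"]), lf = unname(bp["lf"]),
                 hf = unname(bp["hf"]), tp = unname(bp["tp"]),
                 n_beats = length(w$rr), resample_hz = resample_hz,
                 correction_method = sub("^corrected:", "", w$provenance)),
            class = "hrv_result")
}

#' @export
print.hrv_result <- function(x, ...) {
  cat(sprintf(paste0("<hrv_result> %d beats [%s]\n",
                     "  RMSSD %.2f ms  SDNN %.2f ms\n",
                     "  VLF %.1f  LF %.1f  HF %.1f  TP %.1f ms^2\n"),
              x$n_beats, x$correction_method, x$rmssd, x$sdnn,
              x$vlf, x$lf, x$hf, x$tp))
  invisible(x)
}
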