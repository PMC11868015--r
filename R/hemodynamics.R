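#' Heart-rate reserve
#'
#' Fraction of the heart-rate reserve used: `(hr - hr_rest) /
#' (hr_max_lab - hr_rest)`, where `hr_max_lab` is the maximum HR reached in
#' a laboratory VO2max test and `hr_rest` the (self-reported) resting HR.
#' Tables conventionally report the value multiplied by 100.
#'
#' @param hr heart rate in bpm (vectorised).
#' @param hr_rest resting HR in bpm.
#' @param hr_max_lab laboratory maximum HR in bpm.
#' @return Reserve fraction (0 at rest, 1 at lab max).
#' @examples
#' hr_reserve(120, 50, 180) # 70/130
#' @export
hr_reserve <- function(hr, hr_rest, hr_max_lab) {
  if (any(hr_max_lab <= hr_rest)) stop("hr_max_lab must exceed hr_rest")
  (hr - hr_rest) / (hr_max_lab - hr_rest)
}

# instantaneous HR sampled on a 1-Hz grid by linear interpolation of
# 60000/rr against beat time; returns list(t, hr) in s / bpm
.hr_grid <- function(rr, step = 1) {
  stopifnot(inherits(rr, "rr_series"))
  ts <- rr$t / 1000
  hr <- 60000 / rr$rr
  grid <- seq(ts[1], ts[length(ts)], by = step)
  list(t = grid, hr = approx(ts, hr, xout = grid, rule = 2)$y)
}

# 5-s centred mean of instantaneous HR around time point t0 (s)
.hr_at <- function(g, t0, halfspan = 2.5) {
  sel <- g$t >= t0 - halfspan & g$t <= t0 + halfspan
  if (!any(sel)) stop("no HR samples within the averaging span")
  mean(g$hr[sel])
}

.check_gaps <- function(rr, lo, hi, max_gap = 10) {
  ts <- rr$t / 1000
  inw <- ts[ts >= lo & ts <= hi]
  if (length(inw) >= 2 && max(diff(inw)) > max_gap) {
    warning(sprintf("HR gap > %g s inside window [%g, %g] s", max_gap, lo, hi))
  }
  invisible(NULL)
}

#' HR recovery over the 30 s after stopping
#'
#' HR at the stop minus HR 30 s later, each taken as a 5-s mean centred on
#' the time point (instantaneous beat-level HR is too noisy to read at an
#' exact instant).
#'
#' @param rr an [rr_series()] covering `[t_stop, t_stop + 30]` s.
#' @param t_stop stop time in seconds.
#' @return Recovery in bpm (positive when HR falls).
#' @export
hr_recovery <- function(rr, t_stop) {
  ts <- rr$t / 1000
  if (ts[1] > t_stop - 2.5 + 1e-9 || ts[length(ts)] < t_stop + 32.5 - 1e-9) {
    stop("series does not cover the 30-s recovery window")
  }
  g <- .hr_grid(rr)
  .hr_at(g, t_stop) - .hr_at(g, t_stop + 30)
}

#' Per-subject heart-rate summaries around the hill and stop
#'
#' Computes the maximum HR on the climb (5-s smoothed), the time-weighted
#' mean HR during the stop, the time-weighted mean HR over the 5 min
#' following (and including) the stop, and the 30-s HR recovery. Each HR is
#' also expressed as a percentage of the laboratory maximum and as the HR
#' reserve fraction (x100).
#'
#' @param rr an [rr_series()] covering hill start through stop + 5 min.
#' @param events list with `t_hill_start`, `t_stop_start`, `t_stop_end` (s).
#' @param hr_rest,hr_max_lab resting and laboratory-maximum HR (bpm);
#'   optional, `NA` summaries are returned for percent/reserve when absent.
#' @param post_window length of the post-stop window (s); default 300.
#' @return List of class `hr_summary` with fields `hr_max_uphill`,
#'   `mean_hr_stop`, `mean_hr_5min`, `recovery_30s` and, for the first
#'   three, `*_pct` (% of lab max) and `*_reserve` (reserve x100).
#' @export
summarize_hr <- function(rr, events, hr_rest = NA, hr_max_lab = NA,
                         post_window = 300) {
  stopifnot(inherits(rr, "rr_series"))
  ev <- events
  if (!(ev$t_hill_start < ev$t_stop_start && ev$t_stop_start < ev$t_stop_end)) {
    stop("events must be ordered: hill start < stop start < stop end")
  }
  g <- .hr_grid(rr)
  win_mean <- function(lo, hi) {
    sel <- g$t >= lo & g$t <= hi
    if (!any(sel)) stop(sprintf("empty HR window [%g, %g] s", lo, hi))
    mean(g$hr[sel])
  }
  .check_gaps(rr, ev$t_hill_start, ev$t_stop_start + post_window)
  # 5-s rolling mean for the uphill maximum
  sm <- stats::filter(g$hr, rep(1 / 5, 5), sides = 2)
  sel <- g$t >= ev$t_hill_start & g$t <= ev$t_stop_start & !is.na(sm)
  if (!any(sel)) stop("empty uphill window")
  hr_max_uphill <- max(sm[sel])
  mean_hr_stop <- win_mean(ev$t_stop_start, ev$t_stop_end)
  mean_hr_5min <- win_mean(ev$t_stop_start, ev$t_stop_start + post_window)
  recovery <- hr_recovery(rr, ev$t_stop_start)
  pct <- function(hr) if (is.na(hr_max_lab)) NA_real_ else 100 * hr / hr_max_lab
  resv <- function(hr) {
    if (is.na(hr_rest) || is.na(hr_max_lab)) NA_real_
    else 100 * hr_reserve(hr, hr_rest, hr_max_lab)
  }
  structure(list(
    hr_max_uphill = hr_max_uphill, mean_hr_stop = mean_hr_stop,
    mean_hr_5min = mean_hr_5min, recovery_30s = recovery,
    hr_max_uphill_pct = pct(hr_max_uphill),
    mean_hr_stop_pct = pct(mean_hr_stop),
    mean_hr_5min_pct = pct(mean_hr_5min),
    hr_max_uphill_reserve = resv(hr_max_uphill),
    mean_hr_stop_reserve = resv(mean_hr_stop),
    mean_hr_5min_reserve = resv(mean_hr_5min)), class = "hr_summary")
}

#' @export
print.hr_summary <- function(x, ...) {
  cat(sprintf(paste0("<hr_summary> max uphill %.1f bpm (%.1f%% max), ",
                     "stop mean %.1f, 5-min mean %.1f, recovery %.1f bpm\n"),
              x$hr_max_uphill, x$hr_max_uphill_pct, x$mean_hr_stop,
              x$mean_hr_5min, x$recovery_30s))
  invisible(x)
}

#' Blood-pressure and rate-pressure-product derivations
#'
#' Pulse pressure at each site, start-to-hilltop deltas, and the two
#' rate-pressure products: `rpp_max = sbp_thh * hr_max_uphill` and
#' `rpp_mean = sbp_thh * mean_hr_stop` (pressure is measured at the stop,
#' not instantaneously at peak effort, hence the stop-mean pairing).
#'
#' @param sbp_start,dbp_start,sbp_thh,dbp_thh blood pressures in mmHg.
#' @param hr_max_uphill,mean_hr_stop heart rates in bpm (optional; the RPPs
#'   are `NA` when absent).
#' @return List of class `bp_derived`: `pp_start`, `pp_thh`, `delta_sbp`,
#'   `delta_dbp`, `delta_pp` (mmHg), `rpp_max`, `rpp_mean` (bpm x mmHg).
#' @examples
#' bp_derive(135, 80, 235, 105, hr_max_uphill = 170, mean_hr_stop = 142)$pp_thh
#' @export
bp_derive <- function(sbp_start, dbp_start, sbp_thh, dbp_thh,
                      hr_max_uphill = NA, mean_hr_stop = NA) {
  if (dbp_start >= sbp_start || dbp_thh >= sbp_thh) {
    stop("diastolic >= systolic: measurement fault")
  }
  pp_start <- sbp_start - dbp_start
  pp_thh <- sbp_thh - dbp_thh
  structure(list(
    pp_start = pp_start, pp_thh = pp_thh,
    delta_sbp = sbp_thh - sbp_start,
    delta_dbp = dbp_thh - dbp_start,
    delta_pp = pp_thh - pp_start,
    rpp_max = sbp_thh * hr_max_uphill,
    rpp_mean = sbp_thh * mean_hr_stop), class = "bp_derived")
}

#' Aggregate triplicate lactate measurements
#'
#' Returns the mean of the two closest of three replicate measurements.
#' When two pairs are equally close, the pair with the lower mean is used
#' (a message notes the tie).
#'
#' @param values numeric vector of replicate lactate values (mmol/L);
#'   normally three. With fewer than three, the plain mean is returned with
#'   a warning.
#' @return Aggregated lactate in mmol/L.
#' @examples
#' aggregate_lactate(c(1.5, 1.7, 2.5)) # 1.6
#' @export
aggregate_lactate <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  if (any(values <= 0)) stop("lactate values must be positive")
  if (length(values) < 3) {
    warning("fewer than three lactate replicates: using plain mean")
    return(mean(values))
  }
  pairs <- utils::combn(values[1:3], 2)
  gaps <- abs(pairs[1, ] - pairs[2, ])
  means <- colMeans(pairs)
  best <- which(gaps - min(gaps) < 1e-9) # tolerance: equal gaps up to rounding
  if (length(best) > 1) {
    message("lactate tie: two pairs equally close; using the lower-mean pair")
    best <- best[which.min(means[best])]
  }
  means[best]
}
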