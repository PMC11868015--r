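`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an RR-interval series
#'
#' Container for a beat-to-beat interval series. Beat occurrence times are
#' cumulative sums of the intervals from `t0`, so `diff(t) == rr` holds for
#' raw series. Corrected series produced by [apply_correction()] may keep
#' their original beat times (see that function's details).
#'
#' @param rr numeric vector of RR intervals in milliseconds, all positive.
#' @param t0 time of the start of the recording in ms (beat 1 occurs at
#'   `t0 + rr[1]`).
#' @param t optional explicit beat times in ms (strictly increasing); when
#'   omitted they are computed from `rr`.
#' @param provenance character tag, `"raw"` or `"corrected:<method>"`.
#' @return An object of class `rr_series` with elements `rr`, `t`,
#'   `provenance`.
#' @examples
#' s <- rr_series(rep(800, 10))
#' s$t[10] # 8000 ms
#' @export
rr_series <- function(rr, t0 = 0, t = NULL, provenance = "raw") {
  rr <- as.numeric(rr)
  if (length(rr) == 0) stop("empty RR series")
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("all RR intervals must be positive and finite")
  if (is.null(t)) {
    t <- t0 + cumsum(rr)
  } else {
    t <- as.numeric(t)
    if (length(t) != length(rr)) stop("t and rr lengths differ")
    if (any(diff(t) <= 0)) stop("beat times must be strictly increasing")
  }
  structure(list(rr = rr, t = t, provenance = provenance), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.1f s, mean RR %.1f ms [%s]\n",
              length(x$rr), (x$t[length(x$t)] - x$t[1] + x$rr[1]) / 1000,
              mean(x$rr), x$provenance))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr)

# quantile-matched distribution parameters from a printed median + IQR
.dist_from_quartiles <- function(median, q25, q75, dist = c("normal", "lognormal")) {
  dist <- match.arg(dist)
  if (!(q25 <= median && median <= q75)) stop("IQR bounds must satisfy q25 <= median <= q75")
  k <- 2 * qnorm(0.75) # 1.349
  if (dist == "normal") {
    list(dist = dist, mean = median, sd = (q75 - q25) / k)
  } else {
    if (q25 <= 0) stop("log-normal quartiles must be positive")
    list(dist = dist, meanlog = log(median), sdlog = (log(q75) - log(q25)) / k)
  }
}

# sample n values from a quartile-parameterised distribution, optionally
# truncated to [lo, hi] by redrawing
.sample_q <- function(n, par, lo = -Inf, hi = Inf) {
  draw <- function(m) {
    if (par$dist == "normal") rnorm(m, par$mean, par$sd) else rlnorm(m, par$meanlog, par$sdlog)
  }
  x <- draw(n)
  for (it in 1:50) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    x[bad] <- draw(length(bad))
  }
  x[x < lo] <- lo; x[x > hi] <- hi
  x
}
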