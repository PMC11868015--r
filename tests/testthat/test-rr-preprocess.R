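test_that("median-filter detection flags only genuine deviations", {
  # constant series: nothing deviates
  expect_false(any(detect_artifacts(const_series(50))$flags))

  # a single merged (doubled) interval deviates by 100% > 5%
  rr <- rep(800, 41); rr[21] <- 1600
  m <- detect_artifacts(rr_series(rr))
  expect_identical(which(m$flags), 21L)

  # uniform jitter within +/-2% stays under a 5% threshold
  set.seed(11)
  rr2 <- 800 * (1 + runif(200, -0.02, 0.02))
  expect_false(any(detect_artifacts(rr_series(rr2))$flags))
})

test_that("compiled windowed median matches the R reference", {
  set.seed(42)
  for (n in c(15, 64, 301)) {
    rr <- 800 + rnorm(n, 0, 40)
    m <- detect_artifacts(rr_series(rr), window_beats = 11)
    expect_equal(m$local_median, ref_windowed_median(rr, 5), tolerance = 1e-12)
  }
})

test_that("detection input validation", {
  expect_error(detect_artifacts(rr_series(c(700, 800))), "shorter")
  expect_error(detect_artifacts(const_series(5), window_beats = 11), "window_beats")
  expect_error(detect_artifacts(const_series(50), window_beats = 4), "odd")
  expect_error(detect_artifacts(const_series(50), threshold_fraction = 1.5), "threshold")
})

test_that("correction methods behave as specified on a constructed artifact", {
  rr <- rr_series(c(800, 800, 800, 800, 800, 1600, 800, 800, 800, 800, 800))
  mask <- detect_artifacts(rr, window_beats = 5)
  expect_identical(which(mask$flags), 6L)

  lin <- apply_correction(rr, mask, "linear")
  expect_equal(length(lin$rr), length(rr$rr))
  expect_equal(lin$rr[6], 800, tolerance = 1e-9)
  expect_equal(lin$rr[-6], rr$rr[-6]) # unflagged untouched
  expect_equal(lin$provenance, "corrected:linear")

  cub <- apply_correction(rr, mask, "cubic")
  expect_equal(length(cub$rr), length(rr$rr))
  # natural spline through constant neighbours is the constant
  expect_equal(cub$rr[6], 800, tolerance = 1e-6)

  del <- apply_correction(rr, mask, "deletion")
  expect_equal(length(del$rr), length(rr$rr) - 1L)
  expect_equal(sum(del$rr), sum(rr$rr) - 1600)
  expect_equal(diff(del$t), del$rr[-1]) # re-timed consistently

  non <- apply_correction(rr, mask, "none")
  expect_equal(non$rr, rr$rr)
})

test_that("empty mask is the identity for every method", {
  rr <- const_series(80)
  mask <- detect_artifacts(rr)
  for (m in c("none", "deletion", "linear", "cubic", "arima")) {
    out <- apply_correction(rr, mask, m)
    expect_equal(out$rr, rr$rr, info = m)
    expect_equal(out$t, rr$t, info = m)
  }
})

test_that("interpolation is idempotent once re-detection is clean", {
  set.seed(3)
  rr <- 800 + rnorm(120, 0, 4)
  rr[c(40, 41, 77)] <- c(1500, 420, 1700) # two adjacent + one isolated artifact
  s <- rr_series(rr)
  m <- detect_artifacts(s)
  corr <- apply_correction(s, m, "linear")
  m2 <- detect_artifacts(corr)
  expect_false(any(m2$flags))
  corr2 <- apply_correction(corr, m2, "linear")
  expect_equal(corr2$rr, corr$rr)
})

test_that("ARIMA correction forecasts flagged runs and falls back when data are short", {
  set.seed(5)
  rr <- 820 + arima.sim(list(ar = 0.5), 300, sd = 3)
  rr[150:151] <- c(1650, 400)
  s <- rr_series(as.numeric(rr))
  m <- detect_artifacts(s)
  expect_true(all(m$flags[150:151]))
  out <- apply_correction(s, m, "arima")
  expect_equal(length(out$rr), 300L)
  expect_true(all(abs(out$rr[150:151] - 820) < 40)) # forecast near process level
  expect_equal(out$rr[-(150:151)], s$rr[-(150:151)])

  # flagged beats too early for a 60-beat fit: linear fallback still fills them
  rr2 <- c(rep(800, 10), 1600, rep(800, 30))
  s2 <- rr_series(rr2)
  m2 <- detect_artifacts(s2)
  out2 <- apply_correction(s2, m2, "arima")
  expect_equal(out2$rr[11], 800, tolerance = 1e-9)
})

test_that("correction refuses degenerate masks", {
  s <- const_series(20)
  m <- detect_artifacts(s)
  m$flags[] <- TRUE
  expect_error(apply_correction(s, m, "linear"), "all beats")
  m$flags[] <- FALSE
  m$flags[1:10] <- TRUE
  expect_error(apply_correction(s, m, "linear"), "half")
})

test_that("flagged extremes use nearest-value extrapolation with a note", {
  rr <- c(1600, rep(800, 30))
  s <- rr_series(rr)
  m <- detect_artifacts(s, window_beats = 5)
  expect_true(m$flags[1])
  expect_message(out <- apply_correction(s, m, "linear"), "extrapolation")
  expect_equal(out$rr[1], 800, tolerance = 1e-9)
})
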