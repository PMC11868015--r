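test_that("IPFM at constant rate emits metronome beats", {
  s <- ipfm_tachogram(function(t) rep(1000, length(t)), 120)
  expect_equal(length(s$rr), 120L)
  expect_true(all(abs(s$rr - 1000) < 1e-6))
  expect_error(ipfm_tachogram(function(t) 1000 - 10 * t, 200), "positive")
})

test_that("IPFM beat stream tracks the rate trajectory", {
  pf <- race_profile(t_hill_start = 30, t_hill_top = 250, stop_duration = 120,
                     hr_hill_peak_frac = 0.95, recovery_drop_30s = 12)
  s <- generate_rr_series(pf, modulation_spec(noise_sd = 0), hr_max_lab = 180)
  # cumulative RR within one beat of total duration
  dur <- 250 + max(120, 300) + 15
  expect_lt(abs(sum(s$rr) / 1000 - dur), mean(s$rr) / 1000 + 0.1)
  # 60-s segment means within 3 bpm of the trajectory mean
  g <- seq(0, dur - 60, by = 60)
  traj <- hrvrace:::.hr_trajectory(pf, 180)
  for (t0 in g) {
    sel <- s$t / 1000 >= t0 & s$t / 1000 < t0 + 60
    if (sum(sel) < 30) next
    mean_hr <- 60000 / mean(s$rr[sel])
    expect_lt(abs(mean_hr - mean(traj(seq(t0, t0 + 60, 0.5)))), 3)
  }
})

test_that("a single LF modulation component lands its power in the LF band", {
  mod <- modulation_spec(data.frame(freq = 0.10, amp = 40), noise_sd = 0)
  pf <- race_profile(t_hill_start = 10, t_hill_top = 20, stop_duration = 330,
                     hr_baseline_frac = 0.74, hr_hill_peak_frac = 0.75,
                     recovery_drop_30s = 2)
  s <- generate_rr_series(pf, mod, hr_max_lab = 100) # near-constant base
  res <- hrv_window(s, t_start = 30, duration = 300)
  expect_equal(res$lf, 800, tolerance = 0.1)
  expect_lt((res$vlf + res$hf) / res$tp, 0.1)
})

test_that("noiseless single-sinusoid spectral fidelity (>= 90% in band)", {
  set.seed(19)
  cases <- data.frame(freq = c(0.02, 0.1, 0.25), amp = c(25, 15, 8))
  for (k in 1:3) {
    s <- sine_tachogram(cases$freq[k], cases$amp[k], duration = 310)
    rs <- resample_tachogram(extract_window(s, 0, 300))
    bp <- spectral_band_powers(rs)
    band <- c("vlf", "lf", "hf")[k]
    expect_gt(unname(bp[band]) / attr(bp, "variance"), 0.9)
  }
})

test_that("artifact injection conserves time and is seed-deterministic", {
  s <- const_series(1000, 800)
  none <- inject_artifacts(s, rate = 0)
  expect_identical(none$rr$rr, s$rr)
  expect_length(none$positions, 0L)

  inj <- inject_artifacts(s, rate = 0.05, seed = 99)
  expect_equal(nrow(inj$sites), 50L)
  expect_lt(abs(sum(inj$rr$rr) - sum(s$rr)), 1e-6)
  inj2 <- inject_artifacts(s, rate = 0.05, seed = 99)
  expect_identical(inj$rr$rr, inj2$rr$rr)
  expect_identical(inj$positions, inj2$positions)
  expect_true(all(inj$positions >= 1 & inj$positions <= length(inj$rr$rr)))

  expect_error(inject_artifacts(s, rate = 0.45, seed = 1), "overlap")
  expect_error(inject_artifacts(const_series(5), rate = 0.1), "10 beats")
})

test_that("each artifact type has its defining local signature", {
  s <- const_series(100, 800)
  one <- function(type) {
    mix <- c(missed = 0, extra = 0, ectopic = 0); mix[type] <- 1
    inject_artifacts(s, rate = 0.01, mix = mix, seed = 7)
  }
  m <- one("missed")
  expect_equal(length(m$rr$rr), 99L)
  expect_equal(max(m$rr$rr), 1600)
  expect_equal(m$rr$rr[m$sites$index], 1600)

  e <- one("extra")
  expect_equal(length(e$rr$rr), 101L)
  i <- e$sites$index
  expect_equal(e$rr$rr[i] + e$rr$rr[i + 1], 800, tolerance = 1e-9)

  c_ <- one("ectopic")
  expect_equal(length(c_$rr$rr), 100L)
  i <- c_$sites$index
  expect_lt(c_$rr$rr[i], 800)
  expect_equal(c_$rr$rr[i] + c_$rr$rr[i + 1], 1600, tolerance = 1e-9)
})

test_that("power/speed traces encode the walking segment", {
  ev <- list(t_hill_start = 50, t_stop_start = 300, t_stop_end = 420)
  rider <- generate_power_speed(ev, 720, walker = FALSE, seed = 3)
  expect_false(detect_walkers(rider$t, power = rider$watts,
                              hill_window = c(50, 300)))
  walk <- generate_power_speed(ev, 720, walker = TRUE, seed = 3)
  expect_true(detect_walkers(walk$t, power = walk$watts,
                             hill_window = c(50, 300)))
  expect_true(detect_walkers(walk$t, speed = walk$speed_mps,
                             hill_window = c(50, 300)))
})

test_that("simulate_cohort attaches consistent signals and ground truth", {
  cfg <- cohort_config(n_neg = 4, n_pos = 4, seed = 55)
  coh <- simulate_cohort(generate_cohort(cfg), artifact_rate = 0.03)
  expect_length(coh$rr, 8L)
  expect_length(coh$ground_truth$clean_rr, 8L)
  for (id in coh$subjects$subject_id) {
    pos <- coh$ground_truth$artifact_positions[[id]]
    expect_true(all(pos >= 1 & pos <= length(coh$rr[[id]]$rr)))
    # corruption conserves total duration
    expect_lt(abs(sum(coh$rr[[id]]$rr) - sum(coh$ground_truth$clean_rr[[id]]$rr)), 1)
  }
  # deterministic regeneration
  coh2 <- simulate_cohort(generate_cohort(cohort_config(n_neg = 4, n_pos = 4, seed = 55)),
                          artifact_rate = 0.03)
  expect_identical(coh$rr[[1]]$rr, coh2$rr[[1]]$rr)
})
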