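# beat series whose instantaneous HR follows hr_fun (bpm), sampled beat-wise
hr_to_series <- function(hr_fun, duration) {
  ipfm_tachogram(function(t) 60000 / hr_fun(t), duration)
}

test_that("hr_reserve follows its definition and bounds", {
  expect_equal(hr_reserve(50, 50, 180), 0)
  expect_equal(hr_reserve(180, 50, 180), 1)
  expect_equal(hr_reserve(120, 50, 180), 70 / 130, tolerance = 1e-12)
  expect_error(hr_reserve(100, 180, 170), "exceed")
  # strictly increasing in hr
  hr <- seq(60, 180, by = 5)
  expect_true(all(diff(hr_reserve(hr, 50, 190)) > 0))
})

test_that("hr_recovery reads smoothed endpoints 30 s apart", {
  flat <- hr_to_series(function(t) rep(150, length(t)), 60)
  expect_equal(hr_recovery(flat, 10), 0, tolerance = 0.1)

  # linear fall 170 -> 140 over [10, 40] s: endpoint difference close to 30
  # (the 5-s centred means clip the corners of the ramp)
  lin <- hr_to_series(function(t) 170 - pmin(pmax(t - 10, 0), 30), 80)
  expect_equal(hr_recovery(lin, 10), 30, tolerance = 1.5)

  # exponential decay, tau = 60 s, amplitude 30: numeric oracle on the
  # smoothed endpoints, and the closed-form 30 (1 - exp(-0.5)) = 11.8 coarsely
  decay <- function(t) 170 - 30 * (1 - exp(-pmax(t - 10, 0) / 60))
  s <- hr_to_series(decay, 60)
  oracle <- mean(decay(seq(7.5, 12.5, 0.01))) - mean(decay(seq(37.5, 42.5, 0.01)))
  got <- hr_recovery(s, 10)
  expect_equal(got, oracle, tolerance = 0.05)
  expect_equal(got, 30 * (1 - exp(-0.5)), tolerance = 0.06)

  expect_error(hr_recovery(hr_to_series(function(t) rep(150, length(t)), 20), 10),
               "cover")
})

test_that("summarize_hr computes windowed summaries and reserve scalings", {
  ev <- list(t_hill_start = 10, t_stop_start = 120, t_stop_end = 220)
  const <- hr_to_series(function(t) rep(150, length(t)), 430)
  hs <- summarize_hr(const, ev, hr_rest = 50, hr_max_lab = 180)
  expect_equal(hs$hr_max_uphill, 150, tolerance = 0.2)
  expect_equal(hs$mean_hr_stop, 150, tolerance = 0.2)
  expect_equal(hs$mean_hr_5min, 150, tolerance = 0.2)
  expect_equal(hs$recovery_30s, 0, tolerance = 0.2)
  expect_equal(hs$hr_max_uphill_pct, 100 * 150 / 180, tolerance = 0.2)
  expect_equal(hs$mean_hr_stop_reserve, 100 * (150 - 50) / 130, tolerance = 0.2)

  # piecewise: 170 on the climb, 140 afterwards
  pw <- hr_to_series(function(t) ifelse(t < 120, 170, 140), 430)
  hs2 <- summarize_hr(pw, ev)
  expect_equal(hs2$hr_max_uphill, 170, tolerance = 0.5)
  expect_equal(hs2$mean_hr_stop, 140, tolerance = 1.5)

  expect_error(summarize_hr(const, list(t_hill_start = 100, t_stop_start = 90,
                                        t_stop_end = 200)), "ordered")
})

test_that("simulated recovery drop is recovered from the generated series", {
  pf <- race_profile(t_hill_start = 30, t_hill_top = 200, stop_duration = 120,
                     recovery_drop_30s = 12)
  mod <- modulation_spec(noise_sd = 0) # trajectory only
  s <- generate_rr_series(pf, mod, hr_max_lab = 180, seed = 1)
  expect_equal(hr_recovery(s, 200), 12, tolerance = 2)
})

test_that("blood-pressure derivations and RPPs", {
  b <- bp_derive(135, 80, 235, 105, hr_max_uphill = 170, mean_hr_stop = 142)
  expect_equal(b$pp_start, 55)
  expect_equal(b$pp_thh, 130)
  expect_equal(b$delta_sbp, 100)
  expect_equal(b$delta_dbp, 25)
  expect_equal(b$delta_pp, 75)
  expect_equal(b$rpp_max, 235 * 170)
  expect_equal(b$rpp_mean, 235 * 142)
  expect_true(b$rpp_mean <= b$rpp_max)

  same <- bp_derive(140, 90, 140, 90)
  expect_equal(same$delta_sbp, 0); expect_equal(same$delta_pp, 0)

  expect_equal(bp_derive(220, 100, 220, 100, 170, 140)$rpp_max, 37400)
  expect_error(bp_derive(120, 130, 220, 100), "fault")
})

test_that("lactate aggregation picks the closest pair with a low-mean tie rule", {
  expect_equal(aggregate_lactate(c(2, 2, 2)), 2)
  expect_equal(aggregate_lactate(c(1.5, 1.7, 2.5)), 1.6)
  expect_message(v <- aggregate_lactate(c(1.0, 1.4, 1.8)), "tie")
  expect_equal(v, 1.2)
  expect_warning(v2 <- aggregate_lactate(c(2.0, 3.0)), "fewer")
  expect_equal(v2, 2.5)
  expect_error(aggregate_lactate(c(-1, 2, 3)), "positive")
  # output bounded by the inputs
  set.seed(9)
  for (i in 1:25) {
    x <- runif(3, 1, 8)
    expect_true(min(x) <= aggregate_lactate(x) && aggregate_lactate(x) <= max(x))
  }
})
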