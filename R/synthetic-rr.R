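#' Race timing and heart-rate trajectory skeleton
#'
#' Describes one subject's passage over the hill: a flat baseline segment,
#' a climb ending at the measurement stop, the stop itself (mono-exponential
#' HR decay towards a plateau, parameterised by the 30-s drop), and easy
#' riding afterwards. The trajectory is expressed as fractions of the
#' subject's laboratory maximum HR.
#'
#' @param t_hill_start climb start (s from recording start); default 60.
#' @param t_hill_top climb end = stop start (s).
#' @param stop_duration stop length (s).
#' @param post_window length of the analysis window after the stop (s).
#' @param hr_baseline_frac HR before the climb, as a fraction of lab max.
#' @param hr_hill_peak_frac HR at the top of the climb, fraction of lab max.
#' @param recovery_tau time constant of the post-stop HR decay (s).
#' @param recovery_drop_30s HR drop over the first 30 s of the stop (bpm).
#' @param post_rise_bpm HR rise above the stop plateau once riding resumes.
#' @return List of class `race_profile`.
#' @export
race_profile <- function(t_hill_start = 60, t_hill_top = 320,
                         stop_duration = 125, post_window = 300,
                         hr_baseline_frac = 0.80, hr_hill_peak_frac = 0.95,
                         recovery_tau = 60, recovery_drop_30s = 12,
                         post_rise_bpm = 6) {
  if (t_hill_start >= t_hill_top) stop("t_hill_start must precede t_hill_top")
  if (stop_duration <= 0) stop("stop_duration must be positive")
  if (!(hr_baseline_frac > 0 && hr_baseline_frac < hr_hill_peak_frac &&
        hr_hill_peak_frac <= 1.1)) {
    stop("need 0 < hr_baseline_frac < hr_hill_peak_frac <= 1.1")
  }
  structure(as.list(environment()), class = "race_profile")
}

#' Sinusoidal tachogram modulation specification
#'
#' One or more (frequency, RR-amplitude) sinusoids placed in the VLF/LF/HF
#' bands, plus per-beat broadband noise. A latent band power `P` maps to a
#' component amplitude `sqrt(2 P)` (a sinusoid of amplitude A carries power
#' A^2 / 2).
#'
#' @param components data frame with columns `freq` (Hz, in (0, 0.5)) and
#'   `amp` (ms, >= 0); optionally `phase` (radians).
#' @param noise_sd per-beat white-noise standard deviation in ms.
#' @return List of class `modulation_spec`.
#' @export
modulation_spec <- function(components = data.frame(freq = numeric(), amp = numeric()),
                            noise_sd = 3) {
  stopifnot(is.data.frame(components), all(c("freq", "amp") %in% names(components)))
  if (nrow(components)) {
    if (any(components$freq <= 0 | components$freq >= 0.5)) stop("frequencies must lie in (0, 0.5) Hz")
    if (any(components$amp < 0)) stop("amplitudes must be >= 0")
  }
  if (is.null(components$phase)) components$phase <- rep(0, nrow(components))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(components = components, noise_sd = noise_sd),
            class = "modulation_spec")
}

# draw band frequencies/phases for a subject's latent powers
.modulation_from_latents <- function(vlf, lf, hf, noise_sd = 3) {
  comp <- data.frame(
    freq = c(runif(1, 0.010, 0.035), runif(1, 0.06, 0.14), runif(1, 0.18, 0.35)),
    amp = sqrt(2 * c(vlf, lf, hf)),
    phase = runif(3, 0, 2 * pi))
  modulation_spec(comp, noise_sd = noise_sd)
}

#' Generate beats from an instantaneous RR trajectory (IPFM)
#'
#' Integral pulse frequency modulation: the instantaneous rate
#' `r(t) = 1000 / rr_ms(t)` is integrated on a fine grid and a beat is
#' emitted each time the integral crosses an integer (unit area per beat).
#' The resulting beat series is genuinely unevenly spaced, so downstream
#' even resampling is exercised realistically.
#'
#' @param rr_fun function of time (s) returning the instantaneous RR in ms;
#'   must be strictly positive over the whole duration.
#' @param duration total duration in s.
#' @param dt integration step in s; default 0.05.
#' @return An [rr_series()] (provenance `"raw"`).
#' @examples
#' s <- ipfm_tachogram(function(t) rep(1000, length(t)), 120)
#' length(s$rr) # 120 beats of 1000 ms
#' @export
ipfm_tachogram <- function(rr_fun, duration, dt = 0.05) {
  tg <- seq(dt, duration, by = dt)
  rr_inst <- rr_fun(tg)
  if (any(!is.finite(rr_inst)) || any(rr_inst <= 0)) {
    stop("instantaneous RR trajectory must be positive everywhere")
  }
  r <- 1000 / rr_inst                    # beats per second
  Fc <- cumsum(r) * dt
  nb <- floor(Fc[length(Fc)])
  if (nb < 1) stop("duration too short to emit a beat")
  bt <- approx(c(0, Fc), c(0, tg), xout = seq_len(nb))$y
  rr <- diff(c(0, bt)) * 1000
  rr_series(rr, provenance = "raw")
}

# piecewise HR trajectory (bpm) for a race profile
.hr_trajectory <- function(profile, hr_max_lab) {
  pf <- profile
  base <- pf$hr_baseline_frac * hr_max_lab
  peak <- pf$hr_hill_peak_frac * hr_max_lab
  drop_amp <- pf$recovery_drop_30s / (1 - exp(-30 / pf$recovery_tau))
  t_stop <- pf$t_hill_top
  t_se <- t_stop + pf$stop_duration
  hr_at_se <- peak - drop_amp * (1 - exp(-pf$stop_duration / pf$recovery_tau))
  function(t) {
    hr <- numeric(length(t))
    a <- t < pf$t_hill_start
    hr[a] <- base
    b <- t >= pf$t_hill_start & t < t_stop
    hr[b] <- base + (peak - base) * (t[b] - pf$t_hill_start) / (t_stop - pf$t_hill_start)
    c_ <- t >= t_stop & t < t_se
    hr[c_] <- peak - drop_amp * (1 - exp(-(t[c_] - t_stop) / pf$recovery_tau))
    d <- t >= t_se
    hr[d] <- peak - drop_amp * (1 - exp(-(t[d] - t_stop) / pf$recovery_tau)) +
      pf$post_rise_bpm * (1 - exp(-(t[d] - t_se) / 30))
    hr
  }
}

#' Simulate one subject's exercise RR series
#'
#' Builds the piecewise HR trajectory from the race profile, superimposes
#' the sinusoidal band modulation on the instantaneous RR signal, generates
#' beats by IPFM, and finally adds per-beat broadband noise.
#'
#' @param profile a [race_profile()].
#' @param mod a [modulation_spec()].
#' @param hr_max_lab the subject's laboratory maximum HR (bpm).
#' @param seed optional integer seed (phases/noise), for reproducibility.
#' @param dt IPFM integration step (s).
#' @return An [rr_series()] covering `t_hill_top + max(stop_duration,
#'   post_window) + 15` seconds.
#' @export
generate_rr_series <- function(profile, mod, hr_max_lab, seed = NULL, dt = 0.05) {
  stopifnot(inherits(profile, "race_profile"), inherits(mod, "modulation_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  duration <- profile$t_hill_top + max(profile$stop_duration, profile$post_window) + 15
  hr_fun <- .hr_trajectory(profile, hr_max_lab)
  cmp <- mod$components
  rr_fun <- function(t) {
    rr <- 60000 / hr_fun(t)
    if (nrow(cmp)) {
      for (k in seq_len(nrow(cmp))) {
        rr <- rr + cmp$amp[k] * sin(2 * pi * cmp$freq[k] * t + cmp$phase[k])
      }
    }
    rr
  }
  s <- ipfm_tachogram(rr_fun, duration, dt)
  if (mod$noise_sd > 0) {
    rr <- s$rr + rnorm(length(s$rr), 0, mod$noise_sd)
    rr <- pmax(rr, 150) # physiological floor
    s <- rr_series(rr, provenance = "raw")
  }
  s
}

#' Inject beat artifacts with known positions
#'
#' Corrupts an RR series at randomly chosen, non-adjacent sites with three
#' artifact types: `missed` (two adjacent intervals merged into one),
#' `extra` (one interval split in two), and `ectopic` (one interval
#' shortened and the next lengthened by the same amount). Total recording
#' duration is conserved exactly.
#'
#' @param rr an [rr_series()] with at least 10 beats.
#' @param rate fraction of beats corrupted, in `[0, 0.5)`.
#' @param mix named proportions for `missed`, `extra`, `ectopic`; must sum
#'   to 1.
#' @param seed optional integer seed.
#' @return List: `rr` (corrupted [rr_series()]), `positions` (all affected
#'   beat indices in the corrupted series), `sites` (data frame `type`,
#'   `index` with one row per injected artifact).
#' @export
inject_artifacts <- function(rr, rate = 0.02,
                             mix = c(missed = 0.4, extra = 0.3, ectopic = 0.3),
                             seed = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$rr)
  if (n < 10) stop("need at least 10 beats")
  if (rate < 0 || rate >= 0.5) stop("rate must be in [0, 0.5)")
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1")
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  n_art <- round(rate * n)
  if (n_art == 0) {
    return(list(rr = rr, positions = integer(0),
                sites = data.frame(type = character(0), index = integer(0))))
  }
  # candidate sites away from the edges, minimum 3 beats apart
  cand <- sample(seq(4L, n - 4L))
  pos <- integer(0)
  for (i in cand) {
    if (all(abs(i - pos) >= 3)) pos <- c(pos, i)
    if (length(pos) == n_art) break
  }
  if (length(pos) < n_art) stop("artifact rate too high: sites would overlap")
  pos <- sort(pos)
  types <- sample(names(mix), n_art, replace = TRUE, prob = mix)
  frac <- runif(n_art, 0.4, 0.6)     # split point for extra beats
  dshift <- runif(n_art, 0.2, 0.35)  # relative shift for ectopic beats
  new_rr <- rr$rr
  out_idx <- integer(n_art)
  # apply from the last site backwards so earlier indices stay valid
  for (k in rev(seq_len(n_art))) {
    i <- pos[k]
    if (types[k] == "missed") {
      new_rr <- c(new_rr[seq_len(i - 1)], new_rr[i] + new_rr[i + 1],
                  new_rr[-seq_len(i + 1)])
      out_idx[k] <- i
      later <- seq_len(n_art) > k
      out_idx[later] <- out_idx[later] - 1L
    } else if (types[k] == "extra") {
      a <- new_rr[i] * frac[k]
      new_rr <- c(new_rr[seq_len(i - 1)], a, new_rr[i] - a, new_rr[-seq_len(i)])
      out_idx[k] <- i
      later <- seq_len(n_art) > k
      out_idx[later] <- out_idx[later] + 1L
    } else { # ectopic
      d <- dshift[k] * new_rr[i]
      new_rr[i] <- new_rr[i] - d
      new_rr[i + 1] <- new_rr[i + 1] + d
      out_idx[k] <- i
    }
  }
  sites <- data.frame(type = types, index = out_idx, stringsAsFactors = FALSE)
  affected <- unique(sort(unlist(lapply(seq_len(n_art), function(k) {
    if (types[k] == "missed") out_idx[k] else c(out_idx[k], out_idx[k] + 1L)
  }))))
  t0 <- rr$t[1] - rr$rr[1]
  list(rr = rr_series(new_rr, t0 = t0, provenance = "raw"),
       positions = affected, sites = sites)
}

#' Simulate power and speed traces for one subject
#'
#' 1-Hz traces over the recording: steady riding before the climb, the
#' climb itself, zero output during the stop, and easy riding after.
#' Walkers get a contiguous zero-power / walking-speed segment covering
#' `walk_frac` of the climb.
#'
#' @param events list or one-row data frame with `t_hill_start`,
#'   `t_stop_start`, `t_stop_end` (s).
#' @param duration total trace duration (s).
#' @param walker logical; simulate a dismounted segment on the climb.
#' @param walk_frac fraction of the climb walked (default 0.4).
#' @param climb_speed mean climbing speed (m/s); the published hill is
#'   650 m in roughly 260 s, about 2.5 m/s.
#' @param seed optional integer seed.
#' @return Data frame `t`, `watts`, `speed_mps`.
#' @export
generate_power_speed <- function(events, duration, walker = FALSE,
                                 walk_frac = 0.4, climb_speed = 2.5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  t <- seq(0, duration)
  watts <- numeric(length(t)); speed <- numeric(length(t))
  pre <- t < events$t_hill_start
  climb <- t >= events$t_hill_start & t < events$t_stop_start
  stp <- t >= events$t_stop_start & t < events$t_stop_end
  post <- t >= events$t_stop_end
  watts[pre] <- pmax(0, rnorm(sum(pre), 180, 25))
  watts[climb] <- pmax(50, rnorm(sum(climb), 260, 25))
  watts[stp] <- 0
  watts[post] <- pmax(0, rnorm(sum(post), 120, 25))
  speed[pre] <- pmax(0.5, rnorm(sum(pre), 7, 0.5))
  speed[climb] <- pmax(0.5, rnorm(sum(climb), climb_speed, 0.3))
  speed[stp] <- 0
  speed[post] <- pmax(0.5, rnorm(sum(post), 8, 0.5))
  if (walker) {
    ci <- which(climb)
    len <- max(1L, floor(walk_frac * length(ci)))
    start <- ci[1] + floor(0.3 * length(ci))
    seg <- start:min(start + len - 1L, ci[length(ci)])
    watts[seg] <- 0
    speed[seg] <- pmax(0.3, rnorm(length(seg), 1.0, 0.1))
  }
  data.frame(t = t, watts = watts, speed_mps = speed)
}

#' Attach simulated RR, power and speed signals to a cohort
#'
#' Runs the IPFM simulator for every subject of a [generate_cohort()]
#' result, using each subject's latent HRV powers, recovery drop, uphill
#' timing and laboratory maximum HR; injects beat artifacts at the
#' configured rate; and simulates power/speed traces (power only for
#' subjects with a meter).
#'
#' @param cohort an `hrv_cohort` from [generate_cohort()].
#' @param artifact_rate fraction of beats corrupted per subject.
#' @param artifact_mix artifact-type proportions, see [inject_artifacts()].
#' @param noise_sd per-beat broadband noise (ms).
#' @param include_power simulate power/speed traces.
#' @param dt IPFM integration step (s).
#' @return The cohort with `rr` (corrupted series), `power` (traces or
#'   `NULL` per subject) and an extended `ground_truth` (`clean_rr`,
#'   `artifact_positions`, `artifact_sites`).
#' @export
simulate_cohort <- function(cohort, artifact_rate = 0.02,
                            artifact_mix = c(missed = 0.4, extra = 0.3, ectopic = 0.3),
                            noise_sd = 3, include_power = TRUE, dt = 0.05) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  lat <- cohort$ground_truth$subject_latents
  sub <- cohort$subjects
  ev <- cohort$events
  rr_list <- list(); clean_list <- list(); pos_list <- list()
  site_list <- list(); pow_list <- list()
  for (i in seq_len(nrow(sub))) {
    id <- sub$subject_id[i]
    set.seed(lat$rr_seed[i])
    peak_frac <- lat$pct_max_uphill[i] / 100
    pf <- race_profile(
      t_hill_start = ev$t_hill_start[i], t_hill_top = ev$t_stop_start[i],
      stop_duration = ev$t_stop_end[i] - ev$t_stop_start[i],
      # steady riding sits below the subject's own climb peak
      hr_baseline_frac = min(0.80, peak_frac - 0.05),
      hr_hill_peak_frac = peak_frac,
      recovery_drop_30s = lat$hr_recovery_true[i])
    mod <- .modulation_from_latents(lat$vlf_true[i], lat$lf_true[i],
                                    lat$hf_true[i], noise_sd = noise_sd)
    clean <- generate_rr_series(pf, mod, sub$hr_max_lab[i], dt = dt)
    inj <- inject_artifacts(clean, rate = artifact_rate, mix = artifact_mix)
    rr_list[[id]] <- inj$rr
    clean_list[[id]] <- clean
    pos_list[[id]] <- inj$positions
    site_list[[id]] <- inj$sites
    if (include_power) {
      dur <- ev$t_stop_start[i] + 315
      pw <- generate_power_speed(ev[i, ], dur, walker = lat$walker[i])
      if (!lat$power_meter[i]) pw$watts <- NA_real_
      pow_list[[id]] <- pw
    }
  }
  cohort$rr <- rr_list
  cohort$power <- if (include_power) pow_list else NULL
  cohort$ground_truth$clean_rr <- clean_list
  cohort$ground_truth$artifact_positions <- pos_list
  cohort$ground_truth$artifact_sites <- site_list
  cohort$artifact_rate <- artifact_rate
  cohort
}
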