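#' Default per-group cohort distribution parameters
#'
#' Medians and interquartile ranges for each simulated variable, per group
#' (`neg` = CAC-free, `pos` = calcified), as published for the emulated
#' 56-rider cohort. Right-skewed, strictly positive variables (HRV band
#' powers, lactate) use a log-normal law with parameters solved from the
#' median and IQR on the log scale; the rest use a normal law with
#' `sd = IQR / 1.349`, truncated at physiological bounds. Prevalences not
#' published (smoking) carry a documented default.
#'
#' @return Nested list: per variable, `neg`/`pos` = `c(median, q25, q75)`,
#'   plus `dist` and truncation `bounds`; and scalar fields `male_frac`,
#'   `smoker_frac`, `walker_frac`, `power_meter_frac` per group.
#' @export
default_group_params <- function() {
  v <- function(neg, pos, dist = "normal", bounds = c(-Inf, Inf)) {
    list(neg = neg, pos = pos, dist = dist, bounds = bounds)
  }
  list(
    age          = v(c(46, 41, 52),       c(55, 50, 59),       bounds = c(18, 90)),
    bmi          = v(c(24.9, 23.3, 26.1), c(25.1, 23.9, 27.6), bounds = c(15, 45)),
    hr_rest      = v(c(54, 49, 60),       c(48, 45, 61),       bounds = c(30, 100)),
    hr_max_lab   = v(c(180, 173, 187),    c(172, 168, 181),    bounds = c(120, 220)),
    vo2max       = v(c(43.4, 38.0, 49.4), c(38.3, 34.5, 44.9), bounds = c(15, 90)),
    sbp_start    = v(c(135, 130, 150),    c(145, 130, 150),    bounds = c(80, 320)),
    dbp_start    = v(c(80, 80, 90),       c(80, 75, 85),       bounds = c(30, 160)),
    sbp_thh      = v(c(220, 193, 238),    c(235, 225, 245),    bounds = c(80, 320)),
    dbp_thh      = v(c(95, 85, 110),      c(105, 95, 110),     bounds = c(30, 200)),
    lactate_start = v(c(1.7, 1.3, 2.2),   c(1.7, 1.4, 2.1),    dist = "lognormal"),
    lactate_thh  = v(c(4.3, 3.4, 5.8),    c(5.0, 3.9, 6.2),    dist = "lognormal"),
    # band powers capped at physiological ceilings for a post-exercise
    # tachogram (far tails of the published IQRs are not credible beat
    # modulations at RR ~ 400 ms)
    vlf          = v(c(92.6, 58.9, 134.4), c(64.9, 43.1, 94.3), dist = "lognormal",
                     bounds = c(0, 2000)),
    lf           = v(c(12.4, 6.8, 20.2),  c(6.3, 2.4, 11.5),   dist = "lognormal",
                     bounds = c(0, 300)),
    hf           = v(c(2.3, 1.0, 6.4),    c(1.6, 0.9, 3.1),    dist = "lognormal",
                     bounds = c(0, 100)),
    hr_recovery  = v(c(12, 10, 15),       c(11, 8, 14),        bounds = c(2, 40)),
    pct_max_uphill = v(c(94.7, 92.7, 97.9), c(95.4, 93.9, 99.4), bounds = c(70, 110)),
    finish_time  = v(c(241.6, 215.4, 267.8), c(255.3, 227.3, 273.3), bounds = c(120, 480)),
    t_uphill     = v(c(260, 239, 297),    c(290, 247, 320),    bounds = c(150, 600)),
    t_stop       = v(c(129, 101, 179),    c(120, 110, 179),    bounds = c(60, 400)),
    rel_power    = v(c(2.9, 2.4, 3.1),    c(2.8, 2.6, 3.0),    bounds = c(0.5, 6)),
    male_frac    = list(neg = 21 / 31, pos = 20 / 25),
    smoker_frac  = list(neg = 0.10, pos = 0.10),
    walker_frac  = list(neg = 6 / 31, pos = 6 / 25),
    power_meter_frac = list(neg = 38 / 56, pos = 38 / 56)
  )
}

#' Cohort simulation configuration
#'
#' @param n_neg,n_pos subjects per group (CAC-free / calcified); >= 2 each.
#' @param group_params parameter list as from [default_group_params()];
#'   individual entries may be overridden.
#' @param bp_rho latent correlation between start and hill-top blood
#'   pressure draws within a subject.
#' @param seed integer RNG seed; the default is recorded so repeat runs are
#'   bit-identical.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_neg = 31, n_pos = 25,
                          group_params = default_group_params(),
                          bp_rho = 0.5, seed = 20180421) {
  if (n_neg < 2 || n_pos < 2) stop("need at least 2 subjects per group")
  for (nm in setdiff(names(group_params),
                     c("male_frac", "smoker_frac", "walker_frac", "power_meter_frac"))) {
    p <- group_params[[nm]]
    for (g in c("neg", "pos")) {
      q <- p[[g]]
      if (!(q[2] <= q[1] && q[1] <= q[3])) {
        stop(sprintf("invalid IQR ordering for %s (%s): need q25 <= median <= q75", nm, g))
      }
    }
  }
  for (nm in c("male_frac", "smoker_frac", "walker_frac", "power_meter_frac")) {
    pr <- unlist(group_params[[nm]])
    if (any(pr < 0 | pr > 1)) stop(sprintf("%s must be a probability", nm))
  }
  structure(list(n_neg = n_neg, n_pos = n_pos, group_params = group_params,
                 bp_rho = bp_rho, seed = as.integer(seed)),
            class = "cohort_config")
}

# sample one variable for a group of size n
.sample_var <- function(n, p, group) {
  par <- .dist_from_quartiles(p[[group]][1], p[[group]][2], p[[group]][3], p$dist)
  b <- p$bounds %||% c(-Inf, Inf)
  .sample_q(n, par, b[1], b[2])
}

#' Sample blood-pressure and lactate measurements for one group
#'
#' Start and hill-top (THH) pressures are each drawn from their own
#' published distribution, tied by a shared latent (correlation `rho`) so
#' THH exceeds start for systolic pressure in virtually every draw. Draws
#' violating pulse pressure > 0 at either site are redrawn. Three lactate
#' replicates per site are emitted: the log-normal true value plus
#' independent meter noise (`sd` 0.15 mmol/L, floored at 0.1).
#'
#' @param n number of subjects.
#' @param group `"neg"` or `"pos"`.
#' @param params parameter list as from [default_group_params()].
#' @param rho start-to-THH latent correlation.
#' @return Data frame with `sbp_start`, `dbp_start`, `sbp_thh`, `dbp_thh`
#'   and `lactate_start_1..3`, `lactate_thh_1..3`.
#' @export
generate_bp_lactate <- function(n, group = c("neg", "pos"),
                                params = default_group_params(), rho = 0.5) {
  group <- match.arg(group)
  par_of <- function(nm) {
    p <- params[[nm]]
    c(.dist_from_quartiles(p[[group]][1], p[[group]][2], p[[group]][3], p$dist),
      list(bounds = p$bounds %||% c(-Inf, Inf)))
  }
  corr_pair <- function(nm_start, nm_thh) {
    ps <- par_of(nm_start); pt <- par_of(nm_thh)
    z1 <- rnorm(n); z2 <- rnorm(n)
    s <- ps$mean + ps$sd * z1
    th <- pt$mean + pt$sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    cbind(pmin(pmax(s, ps$bounds[1]), ps$bounds[2]),
          pmin(pmax(th, pt$bounds[1]), pt$bounds[2]))
  }
  sb <- corr_pair("sbp_start", "sbp_thh")
  db <- corr_pair("dbp_start", "dbp_thh")
  for (it in 1:50) {
    bad <- which(sb[, 1] - db[, 1] <= 0 | sb[, 2] - db[, 2] <= 0)
    if (!length(bad)) break
    m <- length(bad)
    sbn <- corr_pair("sbp_start", "sbp_thh"); dbn <- corr_pair("dbp_start", "dbp_thh")
    sb[bad, ] <- sbn[seq_len(m), , drop = FALSE]
    db[bad, ] <- dbn[seq_len(m), , drop = FALSE]
  }
  lac <- function(nm) {
    p <- par_of(nm)
    true <- rlnorm(n, p$meanlog, p$sdlog)
    reps <- sapply(1:3, function(i) pmax(0.1, true + rnorm(n, 0, 0.15)))
    list(true = true, reps = matrix(reps, nrow = n))
  }
  ls <- lac("lactate_start"); lt <- lac("lactate_thh")
  out <- data.frame(sbp_start = sb[, 1], dbp_start = db[, 1],
                    sbp_thh = sb[, 2], dbp_thh = db[, 2])
  for (i in 1:3) out[[paste0("lactate_start_", i)]] <- ls$reps[, i]
  for (i in 1:3) out[[paste0("lactate_thh_", i)]] <- lt$reps[, i]
  attr(out, "lactate_true") <- data.frame(start = ls$true, thh = lt$true)
  out
}

#' Generate a synthetic two-group exercise cohort
#'
#' Draws per-subject metadata, event times, blood pressure and lactate, and
#' latent HRV band powers from the per-group distributions in the
#' configuration. Group labels are assigned first; every draw is governed
#' by `config$seed`, so identical configurations reproduce the cohort
#' bit-for-bit. Walkers (riders who dismount on the climb) are chosen per
#' group with probability weights favouring low VO2max, mirroring the
#' observed fitness gap.
#'
#' @param config a [cohort_config()].
#' @return List of class `hrv_cohort`: `subjects` (data frame, one row per
#'   subject), `events` (hill start / stop start / stop end in s), and
#'   `ground_truth` (per-subject latent HRV powers, true lactate, walker
#'   flags, per-subject RR seeds).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  p <- config$group_params
  n <- c(neg = config$n_neg, pos = config$n_pos)
  lab <- c("CAC-", "CAC+")
  groups <- rep(c("neg", "pos"), times = n)
  subj <- NULL; latents <- NULL
  for (g in c("neg", "pos")) {
    m <- n[[g]]
    draw <- function(nm) .sample_var(m, p[[nm]], g)
    age <- draw("age"); bmi <- draw("bmi")
    hr_rest <- draw("hr_rest"); hr_max <- draw("hr_max_lab")
    for (it in 1:50) { # resting HR must sit well below lab max
      bad <- which(hr_max - hr_rest < 40)
      if (!length(bad)) break
      hr_rest[bad] <- .sample_var(length(bad), p$hr_rest, g)
      hr_max[bad] <- .sample_var(length(bad), p$hr_max_lab, g)
    }
    vo2 <- draw("vo2max")
    sex <- ifelse(runif(m) < p$male_frac[[g]], "M", "F")
    smoker <- runif(m) < p$smoker_frac[[g]]
    bp <- generate_bp_lactate(m, g, p, rho = config$bp_rho)
    rec <- draw("hr_recovery"); pctmax <- draw("pct_max_uphill")
    vlf <- draw("vlf"); lf <- draw("lf"); hf <- draw("hf")
    fin <- draw("finish_time"); tup <- draw("t_uphill"); tst <- draw("t_stop")
    relp <- draw("rel_power")
    n_walk <- round(p$walker_frac[[g]] * m)
    walker <- rep(FALSE, m)
    if (n_walk > 0) {
      w <- rank(-vo2) # low fitness -> high weight
      walker[sample.int(m, n_walk, prob = w / sum(w))] <- TRUE
    }
    meter <- runif(m) < p$power_meter_frac[[g]]
    grp_lab <- if (g == "neg") lab[1] else lab[2]
    sdf <- data.frame(group = grp_lab, age = age, sex = sex, bmi = bmi,
                      hr_rest = hr_rest, hr_max_lab = hr_max, vo2max = vo2,
                      smoker = smoker, stringsAsFactors = FALSE)
    sdf <- cbind(sdf, bp)
    sdf$finish_time_min <- fin
    sdf$rel_power_wkg <- relp
    ldf <- data.frame(group = grp_lab, vlf_true = vlf, lf_true = lf,
                      hf_true = hf, hr_recovery_true = rec,
                      pct_max_uphill = pctmax, t_uphill = tup, t_stop = tst,
                      walker = walker, power_meter = meter,
                      stringsAsFactors = FALSE)
    ldf <- cbind(ldf, attr(bp, "lactate_true"))
    subj <- rbind(subj, sdf)
    latents <- rbind(latents, ldf)
  }
  ns <- nrow(subj)
  id <- sprintf("S%03d", seq_len(ns))
  subj <- cbind(subject_id = id, subj, stringsAsFactors = FALSE)
  latents <- cbind(subject_id = id, latents, stringsAsFactors = FALSE)
  events <- data.frame(subject_id = id,
                       t_hill_start = 60,
                       t_stop_start = 60 + latents$t_uphill,
                       t_stop_end = 60 + latents$t_uphill + latents$t_stop)
  latents$rr_seed <- (config$seed + 104729 * seq_len(ns)) %% 2147483647L
  structure(list(subjects = subj, events = events,
                 ground_truth = list(subject_latents = latents),
                 config = config),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  tb <- table(x$subjects$group)
  cat(sprintf("<hrv_cohort> %d subjects (%s)%s\n", nrow(x$subjects),
              paste(names(tb), tb, sep = " = ", collapse = ", "),
              if (!is.null(x$rr)) sprintf(", RR series attached (%d)", length(x$rr)) else ""))
  invisible(x)
}
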