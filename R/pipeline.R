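#' Analysis run configuration
#'
#' @param correction artifact-correction method for the main analysis;
#'   default `"arima"` (the method behind the published HRV table).
#' @param threshold median-filter detection threshold (fraction).
#' @param window_beats median-filter window length (beats, odd).
#' @param window_duration HRV analysis window after the stop (s).
#' @param resample_hz tachogram resampling rate (Hz).
#' @param alpha two-sided significance level.
#' @param walker_power_floor,walker_speed_floor,walker_min_frac walker
#'   detection thresholds, see [detect_walkers()].
#' @param logistic_main,logistic_expanded predictor lists for the two
#'   default logistic models (`NULL` entries keep the built-ins: the
#'   significant hill-top variables, and those plus the classical
#'   atherosclerosis risk factors).
#' @param do_logistic fit the logistic models (disable for speed in
#'   repeated calibration runs).
#' @return List of class `run_config`.
#' @export
run_config <- function(correction = "arima", threshold = 0.05,
                       window_beats = 11, window_duration = 300,
                       resample_hz = 4, alpha = 0.05,
                       walker_power_floor = 0, walker_speed_floor = 1.8,
                       walker_min_frac = 0.2,
                       logistic_main = NULL, logistic_expanded = NULL,
                       do_logistic = TRUE) {
  if (!correction %in% c("none", "deletion", "linear", "cubic", "arima")) {
    stop("unknown correction method: ", correction)
  }
  structure(list(
    correction = correction, threshold = threshold,
    window_beats = window_beats, window_duration = window_duration,
    resample_hz = resample_hz, alpha = alpha,
    walker_power_floor = walker_power_floor,
    walker_speed_floor = walker_speed_floor,
    walker_min_frac = walker_min_frac,
    logistic_main = logistic_main %||%
      c("lf", "sbp_thh", "dbp_thh", "delta_dbp", "delta_pp", "rpp_mean"),
    logistic_expanded = logistic_expanded %||%
      c("lf", "age", "sex_male", "bmi", "hr_max_lab", "vo2max", "smoker",
        "sbp_start", "dbp_start", "delta_dbp"),
    do_logistic = do_logistic), class = "run_config")
}

# variables entering the two comparison tables
.baseline_vars <- c("age", "bmi", "sbp_start", "dbp_start", "pp_start",
                    "hr_rest", "lactate_start", "hr_max_lab", "vo2max")
.thh_vars <- c("finish_time_min", "t_uphill", "t_stop", "rel_power_wkg",
               "hr_max_uphill", "hr_max_uphill_pct", "hr_max_uphill_reserve",
               "hr_recovery_stop", "mean_hr_stop", "mean_hr_stop_pct",
               "mean_hr_stop_reserve", "mean_hr_5min", "mean_hr_5min_pct",
               "mean_hr_5min_reserve",
               "sbp_start", "sbp_thh", "delta_sbp",
               "dbp_start", "dbp_thh", "delta_dbp",
               "pp_start", "pp_thh", "delta_pp",
               "rpp_max", "rpp_mean", "lactate_thh",
               "rmssd", "sdnn", "vlf", "lf", "hf", "tp")

# preprocess + HRV + haemodynamics for one subject; returns a one-row list
.subject_measures <- function(id, sub, ev, rr, config) {
  out <- list(subject_id = id)
  mask <- detect_artifacts(rr, config$window_beats, config$threshold)
  cor <- tryCatch(
    suppressMessages(apply_correction(rr, mask, config$correction)),
    error = function(e) {
      message("subject ", id, ": correction failed (", conditionMessage(e),
              "); HRV cells left missing")
      NULL
    })
  if (is.null(cor)) {
    # HR summaries tolerate residual artifacts (5-s smoothing); HRV does not
    hs_input <- rr
  } else {
    hs_input <- cor
  }
  hrv <- if (is.null(cor)) NULL else tryCatch(
    suppressMessages(hrv_window(cor, ev$t_stop_start, config$window_duration,
                                config$resample_hz)),
    error = function(e) NULL)
  hs <- tryCatch(
    suppressWarnings(summarize_hr(hs_input, as.list(ev), hr_rest = sub$hr_rest,
                                  hr_max_lab = sub$hr_max_lab,
                                  post_window = config$window_duration)),
    error = function(e) NULL)
  if (is.null(hrv) || is.null(hs)) {
    message("subject ", id, ": incomplete RR coverage; HRV/HR cells left missing")
  }
  bp <- tryCatch(
    bp_derive(sub$sbp_start, sub$dbp_start, sub$sbp_thh, sub$dbp_thh,
              hr_max_uphill = hs$hr_max_uphill %||% NA,
              mean_hr_stop = hs$mean_hr_stop %||% NA),
    error = function(e) { message("subject ", id, ": ", conditionMessage(e)); NULL })
  lac <- function(cols) {
    v <- suppressWarnings(as.numeric(sub[cols]))
    if (all(is.na(v))) NA_real_ else suppressMessages(aggregate_lactate(v[!is.na(v)]))
  }
  c(out,
    list(hr_max_uphill = hs$hr_max_uphill %||% NA,
         hr_max_uphill_pct = hs$hr_max_uphill_pct %||% NA,
         hr_max_uphill_reserve = hs$hr_max_uphill_reserve %||% NA,
         hr_recovery_stop = hs$recovery_30s %||% NA,
         mean_hr_stop = hs$mean_hr_stop %||% NA,
         mean_hr_stop_pct = hs$mean_hr_stop_pct %||% NA,
         mean_hr_stop_reserve = hs$mean_hr_stop_reserve %||% NA,
         mean_hr_5min = hs$mean_hr_5min %||% NA,
         mean_hr_5min_pct = hs$mean_hr_5min_pct %||% NA,
         mean_hr_5min_reserve = hs$mean_hr_5min_reserve %||% NA,
         pp_start = bp$pp_start %||% NA, pp_thh = bp$pp_thh %||% NA,
         delta_sbp = bp$delta_sbp %||% NA, delta_dbp = bp$delta_dbp %||% NA,
         delta_pp = bp$delta_pp %||% NA,
         rpp_max = bp$rpp_max %||% NA, rpp_mean = bp$rpp_mean %||% NA,
         lactate_start = lac(paste0("lactate_start_", 1:3)),
         lactate_thh = lac(paste0("lactate_thh_", 1:3)),
         rmssd = hrv$rmssd %||% NA, sdnn = hrv$sdnn %||% NA,
         vlf = hrv$vlf %||% NA, lf = hrv$lf %||% NA,
         hf = hrv$hf %||% NA, tp = hrv$tp %||% NA,
         n_flagged = sum(mask$flags)))
}

#' Run the full group-comparison analysis on a cohort
#'
#' Executes the whole chain for every subject — artifact detection and
#' correction, windowed HRV, HR summaries, blood-pressure derivations,
#' lactate aggregation — then builds the baseline and hill-top comparison
#' tables (median/IQR, Mann-Whitney U, p), the sex chi-square, walker
#' detection with the cyclists-only comparison, and the two multivariable
#' logistic models for CAC status.
#'
#' @param cohort an `hrv_cohort` (with RR series attached, see
#'   [simulate_cohort()]) or a directory written by [write_cohort()].
#' @param config a [run_config()].
#' @return Object of class `hrv_report`: `measures` (per-subject data
#'   frame), `baseline_table`, `thh_table`, `cyclists_table`,
#'   `sex_chisq`, `logistic_main`, `logistic_expanded`, `walkers`,
#'   `config`.
#' @export
run_full_analysis <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "hrv_cohort"), inherits(config, "run_config"))
  if (is.null(cohort$rr)) stop("cohort has no RR series; run simulate_cohort() first")
  sub <- cohort$subjects
  ev <- cohort$events
  if (any(table(sub$group) < 2)) stop("need at least 2 subjects per group")
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    id <- sub$subject_id[i]
    .subject_measures(id, sub[i, ], ev[i, ], cohort$rr[[id]], config)
  })
  meas <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  keep <- setdiff(names(sub), "subject_id")
  meas <- cbind(meas, sub[, keep, drop = FALSE])
  meas$sex_male <- as.integer(meas$sex == "M")
  meas$smoker <- as.integer(meas$smoker)
  meas$t_uphill <- ev$t_stop_start - ev$t_hill_start
  meas$t_stop <- ev$t_stop_end - ev$t_stop_start
  meas$cac <- as.integer(meas$group == "CAC+")
  # CAC-free riders are the reference group whose U is reported
  if (all(meas$group %in% c("CAC-", "CAC+"))) {
    meas$group <- factor(meas$group, levels = c("CAC-", "CAC+"))
  }
  # walker detection from power (preferred) or speed
  walkers <- rep(NA, nrow(meas))
  if (!is.null(cohort$power)) {
    for (i in seq_len(nrow(meas))) {
      pw <- cohort$power[[meas$subject_id[i]]]
      if (is.null(pw)) next
      has_power <- !all(is.na(pw$watts))
      walkers[i] <- suppressMessages(detect_walkers(
        pw$t,
        power = if (has_power) pw$watts else NULL,
        speed = pw$speed_mps,
        hill_window = c(ev$t_hill_start[i], ev$t_stop_start[i]),
        power_floor = config$walker_power_floor,
        speed_floor = config$walker_speed_floor,
        min_frac = config$walker_min_frac))
    }
  }
  meas$walker <- walkers
  baseline <- compare_groups(meas, .baseline_vars, "group", config$alpha)
  thh <- compare_groups(meas, intersect(.thh_vars, names(meas)), "group", config$alpha)
  sex_tab <- table(factor(meas$group, levels = c("CAC-", "CAC+")),
                   factor(meas$sex, levels = c("M", "F")))
  sex_chisq <- tryCatch(chi_square_2x2(unclass(sex_tab)), error = function(e) NULL)
  cyc <- NULL
  cyc_idx <- which(meas$walker %in% FALSE)
  if (length(cyc_idx) && all(table(meas$group[cyc_idx]) >= 2)) {
    cyc <- compare_groups(meas[cyc_idx, ], intersect(.thh_vars, names(meas)),
                          "group", config$alpha)
    gw <- table(factor(meas$group[which(meas$walker %in% TRUE)],
                       levels = c("CAC-", "CAC+")))
    if (any(gw == 0) && sum(gw) > 0) {
      warning("all detected walkers belong to one group; cyclists-only comparison may be imbalanced")
    }
  } else if (any(walkers %in% TRUE)) {
    warning("cyclists-only subgroup smaller than 2 per group; section omitted")
  }
  lmain <- lexp <- NULL
  if (config$do_logistic) {
    lmain <- tryCatch(suppressWarnings(
      fit_logistic(meas, "cac", config$logistic_main)), error = function(e) NULL)
    lexp <- tryCatch(suppressWarnings(
      fit_logistic(meas, "cac", config$logistic_expanded)), error = function(e) NULL)
  }
  meta <- list(package_version = as.character(utils::packageVersion("hrvrace")),
               r_version = R.version.string,
               cohort_seed = cohort$config$seed %||% NA)
  structure(list(measures = meas, baseline_table = baseline, thh_table = thh,
                 cyclists_table = cyc, sex_chisq = sex_chisq,
                 logistic_main = lmain, logistic_expanded = lexp,
                 walkers = walkers, config = config, meta = meta),
            class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  tb <- table(x$measures$group)
  cat(sprintf("=== Cohort: %s ===\n", paste(names(tb), tb, sep = " = ", collapse = ", ")))
  if (!is.null(x$sex_chisq)) {
    cat(sprintf("Sex distribution chi-square: X2 = %.3f, p = %.3f\n",
                x$sex_chisq$statistic, x$sex_chisq$p))
  }
  cat("\n--- Baseline characteristics ---\n"); print(x$baseline_table)
  cat("\n--- Hill-top and post-stop comparison ---\n"); print(x$thh_table)
  if (!is.null(x$cyclists_table)) {
    cat(sprintf("\n--- Cyclists only (n = %d) ---\n", sum(x$walkers %in% FALSE)))
    print(x$cyclists_table)
  }
  if (!is.null(x$logistic_main)) {
    cat("\n--- Logistic model (hill-top variables) ---\n"); print(x$logistic_main)
  }
  if (!is.null(x$logistic_expanded)) {
    cat("\n--- Expanded adjusted logistic model ---\n"); print(x$logistic_expanded)
  }
  invisible(x)
}

#' Cyclists-only comparison from a finished report
#'
#' Repeats the hill-top comparison on the subjects who cycled the whole
#' climb (walker status `FALSE`; unknowns excluded).
#'
#' @param report an `hrv_report` from [run_full_analysis()].
#' @return A `group_comparison` table, or `NULL` when the subgroup is too
#'   small.
#' @export
subgroup_cyclists <- function(report) {
  stopifnot(inherits(report, "hrv_report"))
  report$cyclists_table
}

#' Sensitivity of the LF comparison to the correction method
#'
#' Re-runs detection + correction + windowed HRV + the LF Mann-Whitney test
#' once per correction method, on the full cohort and on the cyclists-only
#' subset, producing the p-value grid used to judge robustness of the LF
#' finding to preprocessing.
#'
#' @param cohort an `hrv_cohort` with RR series.
#' @param config a [run_config()].
#' @param methods correction methods to evaluate.
#' @return Data frame `method`, `p_full`, `p_cyclists` (the latter `NA`
#'   when walker status is unavailable).
#' @export
correction_sensitivity <- function(cohort, config = run_config(),
                                   methods = c("none", "deletion", "linear", "cubic", "arima")) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  if (is.null(cohort$rr)) stop("cohort has no RR series")
  sub <- cohort$subjects; ev <- cohort$events
  masks <- lapply(sub$subject_id, function(id)
    detect_artifacts(cohort$rr[[id]], config$window_beats, config$threshold))
  names(masks) <- sub$subject_id
  # walker flags via the default pipeline route
  base_cfg <- config; base_cfg$do_logistic <- FALSE
  walkers <- if (!is.null(cohort$power)) {
    run_full_analysis(cohort, base_cfg)$walkers
  } else rep(NA, nrow(sub))
  out <- lapply(methods, function(m) {
    lf <- vapply(seq_len(nrow(sub)), function(i) {
      id <- sub$subject_id[i]
      tryCatch({
        cor <- apply_correction(cohort$rr[[id]], masks[[id]], m)
        suppressMessages(hrv_window(cor, ev$t_stop_start[i],
                                    config$window_duration, config$resample_hz))$lf
      }, error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(lf))) {
      return(data.frame(method = m, p_full = NA_real_, p_cyclists = NA_real_))
    }
    g <- sub$group
    p_full <- mann_whitney(lf[g == "CAC-"], lf[g == "CAC+"])$p
    p_cyc <- NA_real_
    cy <- walkers %in% FALSE
    if (sum(cy & g == "CAC-") >= 2 && sum(cy & g == "CAC+") >= 2) {
      p_cyc <- mann_whitney(lf[cy & g == "CAC-"], lf[cy & g == "CAC+"])$p
    }
    data.frame(method = m, p_full = p_full, p_cyclists = p_cyc)
  })
  do.call(rbind, out)
}
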