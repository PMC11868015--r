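#' Median and interquartile range
#'
#' Linear-interpolation quantiles (R type 7), the convention used for all
#' median (IQR) table cells.
#'
#' @param x numeric vector (NAs dropped).
#' @return Named vector `median`, `q25`, `q75`.
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # 2.5, 1.75, 3.25
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no values")
  q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Mann-Whitney U test (two-sided)
#'
#' Reports the U statistic of the first sample (its rank sum minus
#' `n1 (n1 + 1) / 2`, with midranks for ties). The two-sided p-value uses
#' the exact null distribution when `n1 + n2 <= 16` and there are no ties,
#' and otherwise a normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param x,y numeric samples (first sample's U is reported).
#' @return List of class `mw_test`: `U`, `p`, `n1`, `n2`, `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, p = 1/3
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(z))
  if (length(unique(z)) == 1L) {
    warning("all values identical across both samples")
    return(structure(list(U = U, p = 1, n1 = n1, n2 = n2, method = "degenerate"),
                     class = "mw_test"))
  }
  if (!ties && n1 + n2 <= 16) {
    mu <- n1 * n2 / 2
    p <- if (U <= mu) 2 * pwilcox(U, n1, n2) else 2 * (1 - pwilcox(U - 1, n1, n2))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tab <- table(z)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) stop("degenerate variance in normal approximation")
    cc <- 0.5 * sign(U - mu)
    zstat <- (U - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(zstat)))
    method <- "normal"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p, x$method))
  invisible(x)
}

#' Chi-square test for a 2x2 table (Yates-corrected)
#'
#' @param tab 2x2 matrix of non-negative counts; no margin may be zero.
#' @return List with `statistic`, `p`, `df`.
#' @examples
#' chi_square_2x2(matrix(c(21, 10, 20, 5), nrow = 2, byrow = TRUE))$p
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin in table")
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p = ct$p.value, df = unname(ct$parameter))
}

#' Multivariable logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit (no penalty) of a binary outcome on
#' untransformed predictors, reporting per-predictor odds ratios with Wald
#' 95% confidence intervals (`exp(coef +/- 1.96 SE)`) and two-sided Wald
#' p-values. Predictors showing signs of complete separation (|coef| > 15
#' or SE > 100 on the logit scale) are flagged and their OR withheld.
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome name of the binary outcome column (0/1, logical, or a
#'   two-level factor).
#' @param predictors character vector of predictor column names.
#' @return Object of class `logistic_fit`: data frame `table` (term, coef,
#'   se, or, ci_low, ci_high, p, separated), `converged`, `n`, `fit` (the
#'   underlying `glm`).
#' @export
fit_logistic <- function(data, outcome, predictors) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  df <- data[, c(outcome, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  y <- df[[outcome]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  df[[outcome]] <- y
  n <- nrow(df)
  if (n <= 10 * length(predictors)) {
    warning(sprintf("only %d complete cases for %d predictors: fit may be unstable",
                    n, length(predictors)))
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- glm(fml, data = df, family = binomial())
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  sep <- abs(cf) > 15 | se > 100
  zc <- qnorm(0.975)
  tab <- data.frame(
    term = names(cf),
    coef = unname(cf),
    se = unname(se),
    or = ifelse(sep, NA_real_, exp(unname(cf))),
    ci_low = ifelse(sep, NA_real_, exp(unname(cf) - zc * unname(se))),
    ci_high = ifelse(sep, NA_real_, exp(unname(cf) + zc * unname(se))),
    p = ifelse(sep, NA_real_, 2 * pnorm(-abs(unname(cf) / unname(se)))),
    separated = unname(sep),
    stringsAsFactors = FALSE)
  structure(list(table = tab, converged = fit$converged, n = n, fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (n = %d, converged: %s)\n", x$n, x$converged))
  tb <- x$table
  out <- data.frame(term = tb$term,
                    `OR (95%% CI)` = sprintf("%.2f (%.2f-%.2f)", tb$or, tb$ci_low, tb$ci_high),
                    p = signif(tb$p, digits), check.names = FALSE)
  print(out, row.names = FALSE)
  if (any(tb$separated)) {
    cat("separation suspected for:", paste(tb$term[tb$separated], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Detect participants who walked part of the climb
#'
#' A subject is classified as a walker when power output is at or below
#' `power_floor` for a contiguous run covering at least `min_frac` of the
#' climb, or, with no power channel, when speed stays below `speed_floor`
#' for such a run.
#'
#' @param t sample times in s (common to both channels).
#' @param power power output in W, or `NULL` when no meter was fitted.
#' @param speed ground speed in m/s, or `NULL`.
#' @param hill_window `c(t_hill_start, t_stop_start)` in s.
#' @param power_floor power threshold in W (default 0).
#' @param speed_floor speed threshold in m/s (default 1.8, brisk walking).
#' @param min_frac minimum contiguous fraction of the climb (default 0.2).
#' @return `TRUE`/`FALSE`, or `NA` (with a message) when neither channel is
#'   available.
#' @export
detect_walkers <- function(t, power = NULL, speed = NULL, hill_window,
                           power_floor = 0, speed_floor = 1.8, min_frac = 0.2) {
  sel <- t >= hill_window[1] & t <= hill_window[2]
  if (!any(sel)) stop("no samples inside the hill window")
  run_frac <- function(cond) {
    r <- rle(cond)
    if (!any(r$values)) return(0)
    max(r$lengths[r$values]) / length(cond)
  }
  if (!is.null(power)) {
    return(run_frac(power[sel] <= power_floor) >= min_frac)
  }
  if (!is.null(speed)) {
    return(run_frac(speed[sel] < speed_floor) >= min_frac)
  }
  message("no power or speed channel: walker status unknown")
  NA
}

#' Compare variables between two groups
#'
#' For each variable: median (IQR) per group, the first group's Mann-Whitney
#' U, the two-sided p-value, and a significance flag at alpha = 0.05.
#'
#' @param data data frame with one row per subject.
#' @param variables character vector of numeric column names to compare.
#' @param group name of the two-level grouping column; the first level (by
#'   factor order) is the reference whose U is reported.
#' @param alpha significance threshold; default 0.05.
#' @return Data frame of class `group_comparison` with one row per variable.
#' @export
compare_groups <- function(data, variables, group, alpha = 0.05) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("grouping column must have exactly two levels")
  lv <- levels(g)
  rows <- lapply(variables, function(v) {
    x <- data[[v]][g == lv[1]]
    y <- data[[v]][g == lv[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(variable = v, median1 = NA, q25_1 = NA, q75_1 = NA,
                        median2 = NA, q25_2 = NA, q75_2 = NA,
                        U = NA, p = NA, significant = NA))
    }
    m1 <- median_iqr(x); m2 <- median_iqr(y)
    mw <- mann_whitney(x, y)
    data.frame(variable = v,
               median1 = m1["median"], q25_1 = m1["q25"], q75_1 = m1["q75"],
               median2 = m2["median"], q25_2 = m2["q25"], q75_2 = m2["q75"],
               U = mw$U, p = mw$p, significant = mw$p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- lv
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  lv <- attr(x, "groups")
  cat(sprintf("%-22s %-22s %-22s %6s %8s\n", "variable",
              lv[1] %||% "group 1", lv[2] %||% "group 2", "U", "p"))
  for (i in seq_len(nrow(x))) {
    cell <- function(m, a, b) sprintf("%.4g (%.4g-%.4g)", m, a, b)
    cat(sprintf("%-22s %-22s %-22s %6g %8.3g%s\n", x$variable[i],
                cell(x$median1[i], x$q25_1[i], x$q75_1[i]),
                cell(x$median2[i], x$q25_2[i], x$q75_2[i]),
                x$U[i], x$p[i], if (isTRUE(x$significant[i])) " *" else ""))
  }
  invisible(x)
}
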