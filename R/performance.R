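#' Two-sided Student-t critical point
#'
#' Upper alpha/2 quantile of the t distribution, the rejection bound for the
#' two-sided two-sample tests.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return Critical point (positive scalar).
#' @examples
#' t_critical(0.05, 46)  # ~2.01
#' t_critical(0.05, 35)  # ~2.03
#' @export
t_critical <- function(alpha, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(df) || df < 1) stop("df must be >= 1")
  stats::qt(1 - alpha / 2, df)
}

new_ttest_result <- function(variant, mean_a, mean_b, var_a, var_b, n_a, n_b,
                             sp, statistic, df_exact, df, alpha) {
  crit <- t_critical(alpha, df)
  structure(list(variant = variant,
                 means = c(a = mean_a, b = mean_b),
                 variances = c(a = var_a, b = var_b),
                 n = c(a = n_a, b = n_b),
                 pooled_sd = sp,
                 statistic = statistic,
                 df_exact = df_exact,
                 df = df,
                 critical = crit,
                 alpha = alpha,
                 p_value = 2 * stats::pt(-abs(statistic), df_exact),
                 reject = abs(statistic) > crit),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> %s two-sample t-test\n", x$variant))
  cat(sprintf("  means %.4f vs %.4f (n = %d, %d)\n",
              x$means[1], x$means[2], x$n[1], x$n[2]))
  cat(sprintf("  t = %.3f, |t| = %.3f, df = %g, t_crit(%.3g) = %.3f, p = %.4g\n",
              x$statistic, abs(x$statistic), x$df, x$alpha / 2, x$critical,
              x$p_value))
  cat("  decision:", if (x$reject) "reject H0" else "retain H0", "\n")
  invisible(x)
}

check_groups <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (anyNA(a) || anyNA(b)) stop("groups must not contain missing values")
  list(a = a, b = b)
}

#' Pooled-variance two-sample t-test
#'
#' Equal-variance two-sample test: T0 = (mean_A - mean_B) /
#' (Sp * sqrt(1/n_A + 1/n_B)) with the pooled standard deviation
#' Sp^2 = ((n_A - 1) s_A^2 + (n_B - 1) s_B^2) / (n_A + n_B - 2) and
#' df = n_A + n_B - 2. The decision compares |T0| with the two-sided
#' critical point.
#'
#' @param a,b Numeric observation vectors (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @return A `ttest_result`.
#' @export
pooled_t <- function(a, b, alpha = 0.05) {
  g <- check_groups(a, b); a <- g$a; b <- g$b
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  df <- na + nb - 2
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff != 0)
      stop("zero pooled variance with unequal means: statistic undefined")
    stat <- 0
  } else {
    stat <- diff / (sqrt(sp2) * sqrt(1 / na + 1 / nb))
  }
  new_ttest_result("pooled", mean(a), mean(b), va, vb, na, nb,
                   sqrt(sp2), stat, df, df, alpha)
}

#' Welch two-sample t-test with truncated reported df
#'
#' Unequal-variance test: T0 = (mean_A - mean_B) / sqrt(s_A^2/n_A +
#' s_B^2/n_B) with the Welch-Satterthwaite degrees of freedom. The exact
#' (real-valued) df drives the p-value; the reported df is its integer part,
#' the convention used when quoting the critical point from a t table, and
#' the critical point is evaluated at the reported df.
#'
#' @inheritParams pooled_t
#' @return A `ttest_result` with `df_exact` (real) and `df` (truncated).
#' @export
welch_t <- function(a, b, alpha = 0.05) {
  g <- check_groups(a, b); a <- g$a; b <- g$b
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  diff <- mean(a) - mean(b)
  if (se2 == 0) {
    if (diff != 0)
      stop("zero variance in both groups with unequal means: statistic undefined")
    stat <- 0; v <- na + nb - 2
  } else {
    stat <- diff / sqrt(se2)
    v <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  new_ttest_result("welch", mean(a), mean(b), va, vb, na, nb,
                   NA_real_, stat, v, floor(v), alpha)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample K-S test of a group against a normal distribution with the
#' group's own sample mean and SD. With estimated parameters the nominal
#' p-value is conservative (the Lilliefors caveat); it is used here, as in
#' field practice, as a screen before the two-sample t-tests.
#'
#' @param x Numeric vector (>= 3 observations).
#' @param alpha Significance level (default 0.05).
#' @return List of class `normality_result`: `statistic`, `p_value`,
#'   `alpha`, `normal` (TRUE when normality is retained).
#' @export
ks_normality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("normality check needs at least 3 observations")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  structure(list(statistic = unname(kt$statistic),
                 p_value = kt$p.value, alpha = alpha,
                 normal = kt$p.value > alpha),
            class = "normality_result")
}

#' F-ratio test of variance equality
#'
#' Two-sided F test of equal population variances, the branch criterion
#' between the pooled and Welch t statistics.
#'
#' @param a,b Numeric observation vectors (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @return List of class `variance_result`: `statistic` (variance ratio),
#'   `df`, `p_value`, `alpha`, `equal` (TRUE when equality is retained).
#' @export
variance_equality <- function(a, b, alpha = 0.05) {
  g <- check_groups(a, b)
  if (stats::var(g$a) == 0 && stats::var(g$b) == 0)
    return(structure(list(statistic = NA_real_, df = NULL, p_value = 1,
                          alpha = alpha, equal = TRUE),
                     class = "variance_result"))
  vt <- stats::var.test(g$a, g$b)
  structure(list(statistic = unname(vt$statistic),
                 df = unname(vt$parameter),
                 p_value = vt$p.value, alpha = alpha,
                 equal = vt$p.value > alpha),
            class = "variance_result")
}

#' Build the turn-level performance table from segmented turns
#'
#' For each trial, pairs the zero-crossing segments of the selected roll
#' trace with the foot-pressure ratio resampled to the same grid, and records
#' per turn: side, duration, and the maximum outer-foot pressure fraction
#' over the turn (outer = left foot for right turns and vice versa, i.e.
#' (1 + r)/2 on right turns and (1 - r)/2 on left turns for the signed ratio
#' r). Trials whose segment count disagrees with the expected turn count are
#' excluded and listed in the `"excluded"` attribute.
#'
#' @param segments_by_trial Named list of `turn_segments` data frames.
#' @param ratio_by_trial Named list of [ski_ts()] pressure-ratio series on
#'   the same sample grid as the segments.
#' @param expected_turns Expected turn count per trial (scalar or vector).
#' @return Data frame of class `turn_table`: `trial`, `turn`, `side`,
#'   `duration_s`, `max_pressure_ratio`; attribute `"excluded"` names
#'   dropped trials.
#' @export
build_turn_table <- function(segments_by_trial, ratio_by_trial,
                             expected_turns) {
  stopifnot(length(segments_by_trial) == length(ratio_by_trial))
  trials <- names(segments_by_trial)
  if (is.null(trials)) trials <- as.character(seq_along(segments_by_trial))
  expected <- rep_len(expected_turns, length(trials))
  excluded <- character(0)
  rows <- list()
  for (i in seq_along(trials)) {
    seg <- segments_by_trial[[i]]
    if (nrow(seg) != expected[i]) {
      excluded <- c(excluded, trials[i])
      next
    }
    r <- ts_values(ratio_by_trial[[i]])
    maxratio <- vapply(seq_len(nrow(seg)), function(k) {
      lo <- seg$start[k]; hi <- min(seg$end[k], length(r))
      rv <- r[lo:hi]
      rv <- rv[!is.na(rv)]
      if (!length(rv)) return(NA_real_)
      if (seg$side[k] == "R") max((1 + rv) / 2) else max((1 - rv) / 2)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      trial = trials[i], turn = seq_len(nrow(seg)), side = seg$side,
      duration_s = seg$duration_s, max_pressure_ratio = maxratio)
  }
  if (!length(rows))
    stop("no trial matched its expected turn count; nothing to analyze")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("turn_table", "data.frame")
  out
}

#' Lateral-asymmetry analysis of turn performance
#'
#' For each performance measure (turn duration; maximum outer-foot pressure
#' ratio), tests H0: mu_L = mu_R between left and right turns at level
#' `alpha`. Each group is first screened for normality (K-S against the
#' fitted normal) and the two groups for variance equality (two-sided F
#' test); the pooled t statistic is used when variances are judged equal,
#' the Welch statistic otherwise. Decisions compare |t| with the two-sided
#' critical point.
#'
#' @param turn_table A `turn_table` (see [build_turn_table()] or
#'   [load_fixture()]).
#' @param alpha Significance level (default 0.05).
#' @return List of class `asymmetry_analysis`, one element per measure, each
#'   with `normality` (per side), `variance`, and `test` (a `ttest_result`,
#'   group a = left turns, group b = right turns).
#' @export
asymmetry_analysis <- function(turn_table, alpha = 0.05) {
  stopifnot(inherits(turn_table, "data.frame"))
  needed <- c("side", "duration_s", "max_pressure_ratio")
  if (!all(needed %in% names(turn_table)))
    stop("turn table must contain columns: ", paste(needed, collapse = ", "))
  out <- list()
  for (measure in c("duration_s", "max_pressure_ratio")) {
    L <- turn_table[[measure]][turn_table$side == "L"]
    R <- turn_table[[measure]][turn_table$side == "R"]
    L <- L[!is.na(L)]; R <- R[!is.na(R)]
    if (length(L) < 2L || length(R) < 2L)
      stop("need at least 2 turns per side for measure ", measure)
    norm <- list(L = ks_normality(L, alpha), R = ks_normality(R, alpha))
    vt <- variance_equality(L, R, alpha)
    test <- if (vt$equal) pooled_t(L, R, alpha) else welch_t(L, R, alpha)
    out[[measure]] <- list(normality = norm, variance = vt, test = test)
  }
  structure(c(out, list(alpha = alpha)), class = "asymmetry_analysis")
}

#' @export
print.asymmetry_analysis <- function(x, ...) {
  cat("<asymmetry_analysis> H0: mu_L = mu_R, alpha =", x$alpha, "\n")
  for (m in c("duration_s", "max_pressure_ratio")) {
    e <- x[[m]]
    cat(sprintf(
      "  %-18s %-6s |t| = %.2f, df = %g, t_crit = %.2f -> %s\n",
      m, e$test$variant, abs(e$test$statistic), e$test$df, e$test$critical,
      if (e$test$reject) "H0 rejected" else "H0 retained"))
  }
  invisible(x)
}

#' Per-trial total durations from a turn table
#'
#' @param turn_table A `turn_table`.
#' @return Data frame with `trial` and `total_duration_s` (sum of the
#'   trial's turn durations), in table order.
#' @export
total_durations <- function(turn_table) {
  agg <- stats::aggregate(duration_s ~ trial, data = turn_table, FUN = sum)
  names(agg)[2] <- "total_duration_s"
  agg[match(unique(turn_table$trial), agg$trial), , drop = FALSE]
}

#' Adaptation-effect analysis across attempts
#'
#' Correlates the attempt index with the trial's total turn duration:
#' a negative correlation means the skier speeds up over attempts
#' (adaptation to snow and course conditions). Attempts with a missing
#' duration keep their index (the attempt axis is preserved) but contribute
#' no point. Significance of r uses t = r * sqrt(n - 2) / sqrt(1 - r^2).
#'
#' @param attempt_index Integer attempt indices (gaps allowed).
#' @param total_duration_s Total durations, `NA` for missing attempts.
#' @return List of class `adaptation_result`: `r`, `slope`, `intercept`
#'   (OLS of duration on attempt), `t`, `df`, `p_value`, `n`,
#'   `attempt_index`, `total_duration_s`.
#' @export
adaptation_analysis <- function(attempt_index, total_duration_s) {
  if (length(attempt_index) != length(total_duration_s))
    stop("attempt_index and total_duration_s differ in length")
  ok <- !is.na(total_duration_s)
  x <- as.numeric(attempt_index[ok]); y <- as.numeric(total_duration_s[ok])
  if (length(x) < 3L) stop("adaptation analysis needs >= 3 recorded attempts")
  if (stats::sd(y) == 0)
    stop("total durations are constant; correlation undefined")
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  n <- length(x)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  structure(list(r = r,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 t = tval, df = n - 2,
                 p_value = 2 * stats::pt(-abs(tval), n - 2),
                 n = n,
                 attempt_index = as.numeric(attempt_index),
                 total_duration_s = as.numeric(total_duration_s)),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf("<adaptation_result> r = %.3f over %d attempts (df = %d)\n",
              x$r, x$n, x$df))
  cat(sprintf("  OLS: duration = %.3f %+.3f x attempt; t = %.2f, p = %.4g\n",
              x$intercept, x$slope, x$t, x$p_value))
  invisible(x)
}
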