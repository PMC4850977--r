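#' Run the full placement + performance pipeline
#'
#' End-to-end orchestration: pattern-correlation table, correlation-distance
#' clustering, turn-detection screening and location ranking; then, on the
#' selected location's roll trace, zero-crossing turn segmentation, the
#' turn-level performance table, the lateral-asymmetry tests and the
#' adaptation-effect analysis. Every exclusion and branching decision is
#' recorded in the returned `log`.
#'
#' @param x A `ski_session` (from [simulate_session()] or [read_session()])
#'   or a [simulation_config()] (a session is generated from its seed).
#' @param correlation_threshold Strong-correlation cutoff (default 0.80).
#' @param alpha Significance level for all tests (default 0.05).
#' @param window Moving-average window (default 5).
#' @param min_duration_s Minimum turn duration for performance segmentation,
#'   seconds (default 0.5).
#' @param detection_min_duration_s Minimum run length for the detection
#'   table (default 0.5 s; use 0 for raw zero-crossing counting as in
#'   field-style reports).
#' @return A list of class `ski_report`: `placement` (a `placement_report`
#'   with dendrogram), `turn_table`, `asymmetry`, `adaptation`, `log`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(simulation_config(n_trials = 3, seed = 7))
#' rep$placement$selected
#' }
#' @export
run_pipeline <- function(x, correlation_threshold = 0.80, alpha = 0.05,
                         window = 5L, min_duration_s = 0.5,
                         detection_min_duration_s = 0.5) {
  session <- if (inherits(x, "sim_config")) simulate_session(x) else x
  if (!inherits(session, "ski_session"))
    stop("x must be a ski_session or a simulation_config")
  if (!length(session$trials))
    stop("session has no valid trials; nothing to analyze")
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  excluded_attempts <- session$manifest$attempt[session$manifest$status != "valid"]
  if (length(excluded_attempts))
    note("excluded attempts (no recording): ",
         paste(excluded_attempts, collapse = ", "))

  cor_tab <- correlation_table(session, window = window)
  det_tab <- detection_table(session, min_duration_s = detection_min_duration_s,
                             window = window)
  dend <- cluster_locations(cor_tab, mode = "reference")
  placement <- rank_locations(cor_tab, det_tab,
                              correlation_threshold = correlation_threshold,
                              dendrogram = dend)
  selected <- placement$selected
  if (is.na(selected)) {
    selected <- placement$ranking$location[1]
    note("no location passed both screens; falling back to top-ranked ",
         selected)
  }
  note("selected location: ", selected)

  segs <- list(); ratios <- list()
  for (key in names(session$trials)) {
    tr <- session$trials[[key]]
    trace <- moving_average(tr$traces[[selected]], window)
    segs[[key]] <- zero_crossing_segments(trace, min_duration_s)
    r <- foot_pressure_ratio(tr$insole_left, tr$insole_right)
    ratios[[key]] <- resample_to(r, tr$meta$imu_rate_hz)
  }
  expected <- vapply(session$trials, function(tr) tr$meta$n_turns, numeric(1))
  turn_table <- build_turn_table(segs, ratios, expected)
  if (length(attr(turn_table, "excluded")))
    note("trials excluded for segment-count mismatch: ",
         paste(attr(turn_table, "excluded"), collapse = ", "))

  asym <- asymmetry_analysis(turn_table, alpha = alpha)
  for (m in c("duration_s", "max_pressure_ratio"))
    note(m, ": variances judged ",
         if (asym[[m]]$variance$equal) "equal -> pooled t"
         else "unequal -> Welch t",
         " (F p = ", signif(asym[[m]]$variance$p_value, 3), ")")

  totals <- total_durations(turn_table)
  attempt_axis <- session$manifest$attempt
  dur_axis <- rep(NA_real_, length(attempt_axis))
  rec_attempt <- as.integer(sub("attempt_", "", totals$trial))
  dur_axis[match(rec_attempt, attempt_axis)] <- totals$total_duration_s
  if (sum(!is.na(dur_axis)) >= 3L) {
    adapt <- adaptation_analysis(attempt_axis, dur_axis)
    note(sprintf("adaptation: r = %.3f over %d recorded of %d attempts",
                 adapt$r, adapt$n, length(attempt_axis)))
  } else {
    adapt <- NULL
    note("adaptation analysis skipped: fewer than 3 recorded attempts")
  }

  structure(list(placement = placement, turn_table = turn_table,
                 asymmetry = asym, adaptation = adapt, log = log),
            class = "ski_report")
}

#' @export
print.ski_report <- function(x, ...) {
  cat("== ski_report ==\n")
  print(x$placement)
  print(x$asymmetry)
  print(x$adaptation)
  cat("log:\n"); cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

ttest_json <- function(t) {
  list(variant = t$variant, mean_L = unname(t$means[1]),
       mean_R = unname(t$means[2]),
       var_L = unname(t$variances[1]), var_R = unname(t$variances[2]),
       n_L = unname(t$n[1]), n_R = unname(t$n[2]),
       pooled_sd = t$pooled_sd, statistic = t$statistic,
       abs_statistic = abs(t$statistic), df_exact = t$df_exact, df = t$df,
       critical = t$critical, alpha = t$alpha, p_value = t$p_value,
       decision = if (t$reject) "reject H0" else "retain H0")
}

#' Write a pipeline report as JSON
#'
#' Serializes the ranking, flags, test records (with every equation-level
#' intermediate: means, variances, pooled SD, exact and reported df) and the
#' adaptation fit, plus the run log and the dendrogram in Newick form.
#'
#' @param report A `ski_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_json <- function(report, path) {
  stopifnot(inherits(report, "ski_report"))
  asym <- lapply(report$asymmetry[c("duration_s", "max_pressure_ratio")],
                 function(e) list(
                   ks_normality = list(L = e$normality$L[c("statistic", "p_value", "normal")],
                                       R = e$normality$R[c("statistic", "p_value", "normal")]),
                   variance_equality = e$variance[c("statistic", "p_value", "equal")],
                   t_test = ttest_json(e$test)))
  out <- list(
    placement = list(
      selected = report$placement$selected,
      correlation_threshold = report$placement$correlation_threshold,
      ranking = report$placement$ranking,
      dendrogram_newick = if (!is.null(report$placement$dendrogram))
        dendrogram_newick(report$placement$dendrogram) else NULL),
    turn_table = as.data.frame(report$turn_table),
    excluded_trials = attr(report$turn_table, "excluded"),
    asymmetry = asym,
    adaptation = report$adaptation[c("r", "slope", "intercept", "t", "df",
                                     "p_value", "n", "attempt_index",
                                     "total_duration_s")],
    log = report$log)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write a pipeline report as markdown
#'
#' @inheritParams report_json
#' @return `path`, invisibly.
#' @export
report_markdown <- function(report, path) {
  stopifnot(inherits(report, "ski_report"))
  r <- report
  lines <- c(
    "# Sensor placement and turn performance report", "",
    "## Placement", "",
    paste0("Selected location: **", r$placement$selected, "** (threshold ",
           r$placement$correlation_threshold, ")"), "",
    "| location | median r | strong | perfect detection | midline |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %s | %s | %s |",
            r$placement$ranking$location,
            r$placement$ranking$median_correlation,
            r$placement$ranking$strong_correlation,
            r$placement$ranking$perfect_detection,
            r$placement$ranking$midline),
    "", "## Lateral asymmetry", "",
    "| measure | variant | abs t | df | t crit | decision |",
    "|---|---|---|---|---|---|")
  for (m in c("duration_s", "max_pressure_ratio")) {
    t <- r$asymmetry[[m]]$test
    lines <- c(lines, sprintf("| %s | %s | %.2f | %g | %.2f | %s |",
                              m, t$variant, abs(t$statistic), t$df,
                              t$critical,
                              if (t$reject) "H0 rejected" else "H0 retained"))
  }
  lines <- c(lines, "", "## Adaptation", "",
             if (is.null(r$adaptation)) "not computed (fewer than 3 recorded attempts)"
             else sprintf("r = %.3f (t = %.2f, df = %d, p = %.4g); slope %.3f s/attempt",
                          r$adaptation$r, r$adaptation$t, r$adaptation$df,
                          r$adaptation$p_value, r$adaptation$slope),
             "", "## Log", "", paste0("- ", r$log))
  writeLines(lines, path)
  invisible(path)
}
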