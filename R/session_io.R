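#' Write a time series as a trace CSV
#'
#' Plain two-column CSV (`time_s`, `value`), the interchange format for all
#' roll-angle traces.
#'
#' @param series A [ski_ts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(series, path) {
  stopifnot(inherits(series, "ski_ts"))
  df <- data.frame(time_s = ts_time(series), value = series$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace CSV
#'
#' Expects columns `time_s` and `value` with strictly increasing time at a
#' nominal uniform rate. Up to 1% timestamp jitter is tolerated silently;
#' larger (but still monotone) jitter is regularized onto the nominal grid
#' with a warning. Non-monotone time fails with the offending line number.
#'
#' @param path CSV file path.
#' @param label Optional label for the resulting series (defaults to the
#'   file name).
#' @return A [ski_ts()].
#' @export
read_trace_csv <- function(path, label = NULL) {
  if (!file.exists(path)) stop("trace file does not exist: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (!nrow(df)) stop("trace file is empty: ", path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace file ", path, " must have columns time_s and value")
  t <- df$time_s
  if (length(t) < 2L) stop("trace file ", path, " has fewer than 2 samples")
  dt <- diff(t)
  bad <- which(dt <= 0)
  if (length(bad))
    stop("non-monotone time in ", path, " at line ", bad[1] + 2L,
         " (header is line 1)")
  dt_nom <- stats::median(dt)
  jitter <- max(abs(dt - dt_nom)) / dt_nom
  if (jitter > 0.01)
    warning("timestamp jitter of ", signif(jitter * 100, 2), "% in ", path,
            "; regularizing onto a uniform ", signif(1 / dt_nom, 6),
            " Hz grid")
  ski_ts(df$value, rate_hz = 1 / dt_nom, t0 = t[1],
         label = if (is.null(label)) basename(path) else label)
}

#' Write / read an insole stream CSV
#'
#' Columns `time_s`, `cell_01` ... `cell_13`.
#'
#' @param stream An [insole_stream()].
#' @param path File path.
#' @return `path` invisibly (write); an [insole_stream()] (read).
#' @export
write_insole_csv <- function(stream, path) {
  stopifnot(inherits(stream, "insole_stream"))
  t <- stream$t0 + (seq_len(nrow(stream$cells)) - 1L) / stream$rate_hz
  df <- data.frame(time_s = t, stream$cells)
  names(df) <- c("time_s", sprintf("cell_%02d", 1:13))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_insole_csv
#' @param foot `"L"` or `"R"` for the stream being read.
#' @export
read_insole_csv <- function(path, foot) {
  if (!file.exists(path)) stop("insole file does not exist: ", path)
  df <- utils::read.csv(path)
  cell_cols <- grep("^cell_", names(df))
  if (length(cell_cols) != 13L)
    stop("insole file ", path, " must have 13 cell_* columns")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-monotone time in ", path)
  insole_stream(as.matrix(df[, cell_cols]), foot,
                rate_hz = 1 / stats::median(dt), t0 = df$time_s[1])
}

#' Write a session to disk
#'
#' Creates one directory per recorded attempt containing a trace CSV per
#' location plus the two insole CSVs, a `manifest.json` describing every
#' attempt (including excluded ones), and, when present, the generator's
#' ground truth as `ground_truth.json`.
#'
#' @param session A `ski_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ski_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_len(nrow(session$manifest))) {
    a <- session$manifest$attempt[i]
    status <- session$manifest$status[i]
    entry <- list(attempt = a, status = status,
                  n_turns = session$manifest$n_turns[i])
    if (status == "valid") {
      key <- paste0("attempt_", a)
      tr <- session$trials[[key]]
      sub <- file.path(dir, key)
      dir.create(sub, showWarnings = FALSE)
      traces <- list()
      for (loc in names(tr$traces)) {
        f <- file.path(key, paste0(loc, ".csv"))
        write_trace_csv(tr$traces[[loc]], file.path(dir, f))
        traces[[loc]] <- f
      }
      entry$traces <- traces
      entry$insole_left <- file.path(key, "insole_left.csv")
      entry$insole_right <- file.path(key, "insole_right.csv")
      write_insole_csv(tr$insole_left, file.path(dir, entry$insole_left))
      write_insole_csv(tr$insole_right, file.path(dir, entry$insole_right))
    }
    entries[[i]] <- entry
  }
  manifest <- list(imu_rate_hz = session$trials[[1]]$meta$imu_rate_hz,
                   pressure_rate_hz = session$trials[[1]]$meta$pressure_rate_hz,
                   attempts = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(session$ground_truth))
    jsonlite::write_json(session$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from disk
#'
#' Inverse of [write_session()]; validates that every valid attempt's files
#' exist.
#'
#' @param dir Session directory containing `manifest.json`.
#' @return A `ski_session` (without generator config; ground truth attached
#'   when the sidecar file is present).
#' @export
read_session <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  trials <- list()
  rows <- list()
  for (entry in manifest$attempts) {
    rows[[length(rows) + 1L]] <- data.frame(attempt = entry$attempt,
                                            status = entry$status,
                                            n_turns = entry$n_turns)
    if (entry$status != "valid") next
    traces <- lapply(entry$traces, function(f) {
      p <- file.path(dir, f)
      if (!file.exists(p)) stop("manifest references missing file: ", p)
      read_trace_csv(p)
    })
    for (loc in names(traces)) traces[[loc]]$label <- loc
    tr <- structure(list(
      traces = traces,
      insole_left = read_insole_csv(file.path(dir, entry$insole_left), "L"),
      insole_right = read_insole_csv(file.path(dir, entry$insole_right), "R"),
      meta = list(attempt = entry$attempt, n_turns = entry$n_turns,
                  imu_rate_hz = manifest$imu_rate_hz,
                  pressure_rate_hz = manifest$pressure_rate_hz)),
      class = "trial_recording")
    trials[[paste0("attempt_", entry$attempt)]] <- tr
  }
  gt_file <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_file))
    jsonlite::read_json(gt_file, simplifyVector = TRUE) else NULL
  structure(list(trials = trials, manifest = do.call(rbind, rows),
                 ground_truth = gt, config = NULL),
            class = "ski_session")
}

# md5 checksums of the packaged fixtures, pinned at build time
.fixture_md5 <- c(
  table4 = "9b08bac2a46c5395abde90102577a33b",
  table6 = "e97963c86429d291403ee2bd06757e89")

#' Load a packaged reference fixture
#'
#' Two fixtures ship with the package, transcribed from the study's printed
#' performance tables: `"table4"`, the 48-turn performance table (8 trials x
#' 6 turns: side, duration, max outer-foot pressure ratio), and `"table6"`,
#' the 9-slot attempt record (attempt index, self-assessment score, total
#' duration; the second attempt was discarded and has no duration). Files are
#' checksum-verified on load.
#'
#' @param name `"table4"` or `"table6"`.
#' @return `"table4"`: a `turn_table` data frame with 48 rows. `"table6"`: a
#'   data frame with columns `attempt`, `trial_label`, `self_assessment`,
#'   `total_duration_s` (one `NA`).
#' @examples
#' t4 <- load_fixture("table4")
#' nrow(t4)
#' @export
load_fixture <- function(name = c("table4", "table6")) {
  name <- match.arg(name)
  file <- switch(name,
                 table4 = "table4_turn_performance.csv",
                 table6 = "table6_attempts.csv")
  path <- system.file("extdata", file, package = "skiturns", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (md5 != .fixture_md5[[name]])
    stop("fixture ", name, " fails its checksum (", md5, "); reinstall the package")
  df <- utils::read.csv(path)
  if (name == "table4") {
    class(df) <- c("turn_table", "data.frame")
  }
  df
}
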