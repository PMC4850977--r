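#' Uniformly sampled scalar time series
#'
#' Lightweight container used for every one-dimensional signal in the package:
#' roll-angle traces from individual IMU locations and the derived foot
#' pressure ratio. Samples are assumed equally spaced at `rate_hz`.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param rate_hz Sampling rate in samples per second (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param label Free-text label used in error messages and plots.
#'
#' @return An object of class `ski_ts`: a list with elements `values`,
#'   `rate_hz`, `t0` and `label`.
#' @examples
#' x <- ski_ts(sin(seq(0, 2 * pi, length.out = 200)), rate_hz = 100)
#' length(x$values)
#' @export
ski_ts <- function(values, rate_hz, t0 = 0, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time series must contain at least one sample")
  if (!all(is.finite(values))) stop("time series '", label, "' contains non-finite values")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  structure(list(values = values, rate_hz = as.numeric(rate_hz),
                 t0 = as.numeric(t0), label = as.character(label)),
            class = "ski_ts")
}

#' @export
print.ski_ts <- function(x, ...) {
  cat(sprintf("<ski_ts> %s: %d samples @ %g Hz, t0 = %g s, span %.3f s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$rate_hz, x$t0,
              (length(x$values) - 1L) / x$rate_hz))
  invisible(x)
}

#' @export
length.ski_ts <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param x A [ski_ts()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "ski_ts"))
  x$t0 + (seq_along(x$values) - 1L) / x$rate_hz
}

# Accept either a ski_ts or a bare numeric vector in the signal operations.
ts_values <- function(x) {
  if (inherits(x, "ski_ts")) x$values else as.numeric(x)
}

#' Insole pressure stream
#'
#' One foot's insole recording: a matrix with one row per time step and one
#' column per pressure cell (13 cells per insole), pressures in N/cm^2.
#'
#' @param cells Numeric matrix, rows = time steps, 13 columns.
#' @param foot `"L"` or `"R"`.
#' @param rate_hz Sampling rate in Hz.
#' @param t0 Time of the first row in seconds.
#'
#' @return An object of class `insole_stream`.
#' @export
insole_stream <- function(cells, foot, rate_hz, t0 = 0) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 13L)
    stop("an insole stream must have exactly 13 pressure cells, got ", ncol(cells))
  if (any(cells < 0)) stop("insole cell pressures must be non-negative")
  foot <- match.arg(foot, c("L", "R"))
  if (rate_hz <= 0) stop("rate_hz must be positive")
  structure(list(cells = cells, foot = foot, rate_hz = as.numeric(rate_hz),
                 t0 = as.numeric(t0)),
            class = "insole_stream")
}

#' @export
print.insole_stream <- function(x, ...) {
  cat(sprintf("<insole_stream> foot %s: %d frames x 13 cells @ %g Hz\n",
              x$foot, nrow(x$cells), x$rate_hz))
  invisible(x)
}
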