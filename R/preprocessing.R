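#' Centered moving average with truncated edge windows
#'
#' Smooths a signal with a centered mean over `window` samples. At the series
#' ends the window shrinks to the available samples, so the output has the
#' same length as the input. The five-point window is the conventional choice
#' for on-snow roll-angle data.
#'
#' @param series A [ski_ts()] or numeric vector.
#' @param window Odd window length in samples (default 5); must not exceed the
#'   series length.
#' @return Smoothed series of the same type and length as the input.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5, 6, 7), window = 5)
#' @export
moving_average <- function(series, window = 5L) {
  v <- ts_values(series)
  n <- length(v)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window %% 2L == 0L)
    stop("moving_average requires an odd window so the mean is centered; got ",
         window)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(series, "ski_ts"))
    ski_ts(out, series$rate_hz, series$t0, series$label)
  else out
}

#' Standard-score normalization
#'
#' Centers and scales a series to sample mean 0 and sample standard deviation
#' 1 (n - 1 denominator). Constant series have no defined standard score and
#' are rejected.
#'
#' @param series A [ski_ts()] or numeric vector with at least 2 samples.
#' @return Normalized series of the same type and length.
#' @examples
#' zscore(c(2, 4, 6))
#' @export
zscore <- function(series) {
  v <- ts_values(series)
  if (length(v) < 2L) stop("zscore requires at least 2 samples")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    lab <- if (inherits(series, "ski_ts") && nzchar(series$label))
      series$label else "series"
    stop("cannot z-score constant ", lab, " (zero standard deviation)")
  }
  out <- (v - mean(v)) / s
  if (inherits(series, "ski_ts"))
    ski_ts(out, series$rate_hz, series$t0, series$label)
  else out
}

#' Foot pressure ratio from paired insole streams
#'
#' Per time step, sums the 13 cells of each insole and forms the signed
#' contrast r = (F_L - F_R) / (F_L + F_R). The ratio is +1 when all force is
#' on the left foot and -1 when all is on the right, so it co-varies
#' positively with a rightward lean (right turn, left/outer foot loaded).
#' Samples whose two-foot total falls below `total_floor` carry no weight
#' information and are set to `NA` (flagged in the `"valid"` attribute).
#'
#' @param left,right [insole_stream()] objects of equal length and rate.
#' @param total_floor Minimum two-foot total force (N/cm^2 summed over cells)
#'   for a sample to be considered valid. Default 1.
#' @return A [ski_ts()] of ratios in \[-1, 1\] at the insole rate, with a
#'   logical attribute `"valid"`.
#' @export
foot_pressure_ratio <- function(left, right, total_floor = 1) {
  stopifnot(inherits(left, "insole_stream"), inherits(right, "insole_stream"))
  if (left$foot != "L" || right$foot != "R")
    stop("arguments must be the left and right insole streams, in that order")
  if (nrow(left$cells) != nrow(right$cells))
    stop("insole streams differ in length (", nrow(left$cells), " vs ",
         nrow(right$cells), ")")
  if (left$rate_hz != right$rate_hz)
    stop("insole streams differ in sampling rate")
  fl <- rowSums(left$cells)
  fr <- rowSums(right$cells)
  total <- fl + fr
  if (all(total == 0))
    stop("total foot force is zero over the whole stream; no ratio defined")
  valid <- total >= total_floor
  r <- rep(NA_real_, length(total))
  r[valid] <- (fl[valid] - fr[valid]) / total[valid]
  out <- structure(list(values = r, rate_hz = left$rate_hz, t0 = left$t0,
                        label = "foot_pressure_ratio"),
                   class = "ski_ts")
  attr(out, "valid") <- valid
  out
}

#' Resample a series onto a new uniform grid by linear interpolation
#'
#' Used to reconcile the 50 Hz insole stream with the 100 Hz IMU grid before
#' computing pattern correlations. The new grid starts at the series origin
#' and never extends beyond the last original sample (no extrapolation).
#'
#' @param series A [ski_ts()].
#' @param target_rate_hz Target sampling rate in Hz.
#' @return A [ski_ts()] at `target_rate_hz`.
#' @export
resample_to <- function(series, target_rate_hz) {
  stopifnot(inherits(series, "ski_ts"))
  if (target_rate_hz <= 0) stop("target_rate_hz must be positive")
  if (target_rate_hz == series$rate_hz) return(series)
  n <- length(series$values)
  span <- (n - 1L) / series$rate_hz
  n_new <- floor(span * target_rate_hz) + 1L
  if (n_new < 1L) stop("target grid over the series span is empty")
  t_old <- ts_time(series)
  t_new <- series$t0 + (seq_len(n_new) - 1L) / target_rate_hz
  v <- series$values
  if (anyNA(v)) {
    # interpolate across flagged-invalid gaps before regridding
    ok <- !is.na(v)
    if (sum(ok) < 2L) stop("too few valid samples to resample")
    v <- stats::approx(t_old[ok], v[ok], xout = t_old, rule = 2)$y
  }
  out <- stats::approx(t_old, v, xout = t_new)$y
  ski_ts(out, target_rate_hz, series$t0, series$label)
}
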