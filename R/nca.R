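# Non-compartmental exposure summaries: linear-trapezoid AUC, log-linear
# terminal half-life, and exposure ratios between tumor models.

#' Trapezoidal area under a concentration-time curve
#'
#' Linear trapezoid on the window `[t_start, t_end]`, with linear
#' interpolation at window edges that fall between samples.  Linear (not
#' log) trapezoids are used throughout because sparse destructive designs
#' with values near zero make the log-trapezoid unstable.
#'
#' @param curve Data frame with columns `time` and `value`, or a numeric
#'   vector of times (then supply `values`).
#' @param t_start,t_end AUC window, days; must lie within the curve support.
#' @param values Concentrations, if `curve` is a time vector.
#' @return AUC in concentration x day units.
#' @export
auc_trapezoid <- function(curve, t_start = NULL, t_end = NULL, values = NULL) {
  if (is.data.frame(curve)) {
    times <- curve$time
    values <- curve$value
  } else {
    times <- curve
  }
  if (length(times) < 2 || length(times) != length(values)) {
    stop("need at least two (time, value) pairs")
  }
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (is.null(t_start)) t_start <- times[1]
  if (is.null(t_end)) t_end <- times[length(times)]
  if (t_start < times[1] || t_end > times[length(times)] || t_end <= t_start) {
    stop("AUC window [", t_start, ", ", t_end,
         "] outside curve support or empty")
  }
  grid <- sort(unique(c(t_start, t_end, times[times > t_start & times < t_end])))
  v <- stats::approx(times, values, xout = grid)$y
  sum(diff(grid) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Terminal half-life by log-linear regression
#'
#' Half-life from the slope of `log(value)` against time over the last
#' `n_points` samples.  A negative half-life (rising terminal phase) is
#' returned as a negative number so callers can flag it.
#'
#' @param curve Data frame with `time` and `value` columns.
#' @param n_points Number of terminal samples to regress on (default 3,
#'   matching a four-point destructive design).
#' @return Half-life in days; negative if the terminal phase is rising.
#' @export
terminal_half_life <- function(curve, n_points = 3) {
  if (n_points < 2) stop("need at least two terminal points")
  n <- nrow(curve)
  if (n < n_points) stop("curve has fewer than n_points samples")
  tail_idx <- seq(n - n_points + 1, n)
  y <- curve$value[tail_idx]
  if (any(y <= 0)) stop("non-positive values in the terminal window")
  slope <- stats::coef(stats::lm(log(y) ~ curve$time[tail_idx]))[2]
  unname(-log(2) / slope)
}

#' Exposure ratio between two curves
#'
#' Ratio of trapezoidal AUCs over a common window, e.g. tumor AUC(0-7 d) of
#' an analyte in the high- versus low-antigen tumor model.
#'
#' @param curve_A,curve_B Data frames with `time` and `value`.
#' @param window Length-2 numeric window in days.
#' @return `AUC_A / AUC_B`.
#' @export
exposure_ratio <- function(curve_A, curve_B, window = c(0, 7)) {
  a <- auc_trapezoid(curve_A, window[1], window[2])
  b <- auc_trapezoid(curve_B, window[1], window[2])
  if (b == 0) stop("denominator AUC is zero")
  a / b
}
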