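# Automatic segmentation of the bolus passage into the four physiological
# time intervals: baseline (BLP), inflow (IFP), outflow (OFP) and reperfusion
# (RPP).

#' Bolus passage phases
#'
#' Holds the landmark time indices of the bolus passage and the induced
#' partition of the time axis (all indices 1-based):
#' * `BLP = [t_first, toa)` — baseline, before contrast arrival;
#' * `IFP = [toa, t_peak]` — inflow, arrival up to the concentration peak;
#' * `OFP = (t_peak, t_min]` — outflow, down to the first post-peak local
#'   minimum;
#' * `RPP = (t_min, t_end]` — reperfusion/recirculation.
#'
#' The four intervals partition `t_first..t_end` and each contains at least
#' one time point.
#'
#' @param toa Time-of-arrival index.
#' @param t_peak Index of the concentration maximum.
#' @param t_min Index of the first local minimum after the peak.
#' @param t_end Last time index.
#' @param t_first First time index (default 1).
#' @return An object of class `bolus_phases` with fields `t_first`, `toa`,
#'   `t_peak`, `t_min`, `t_end` and `interval_of`, a factor mapping every
#'   time index to its interval.
#' @export
bolus_phases <- function(toa, t_peak, t_min, t_end, t_first = 1L) {
  toa <- as.integer(toa); t_peak <- as.integer(t_peak)
  t_min <- as.integer(t_min); t_end <- as.integer(t_end)
  t_first <- as.integer(t_first)
  if (!(t_first < toa && toa < t_peak && t_peak < t_min && t_min < t_end))
    stop(sprintf(
      "invalid phase landmarks: need t_first < toa <= t_peak < t_min < t_end, got (%d, %d, %d, %d, %d)",
      t_first, toa, t_peak, t_min, t_end))
  idx <- t_first:t_end
  interval_of <- factor(
    ifelse(idx < toa, "BLP",
           ifelse(idx <= t_peak, "IFP",
                  ifelse(idx <= t_min, "OFP", "RPP"))),
    levels = INTERVALS)
  structure(list(t_first = t_first, toa = toa, t_peak = t_peak,
                 t_min = t_min, t_end = t_end, interval_of = interval_of),
            class = "bolus_phases")
}

#' @export
print.bolus_phases <- function(x, ...) {
  cat(sprintf("<bolus_phases> TOA %d, peak %d, post-peak minimum %d (of %d time points)\n",
              x$toa, x$t_peak, x$t_min, x$t_end))
  tab <- table(x$interval_of)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

moving_average_reflect <- function(x, width) {
  if (width <= 1L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  padded <- c(rev(x[seq_len(h) + 1L]), x, rev(x[n - seq_len(h)]))
  as.numeric(stats::filter(padded, rep(1 / width, width), sides = 2L))[h + seq_len(n)]
}

#' Detect the bolus passage phases on a concentration curve
#'
#' Numerical analysis of the time-dependent bolus passage function of the
#' reference region:
#' 1. the curve is smoothed with a centred moving average of width
#'    `smooth_width` (reflected ends; `smooth_width = 1` disables smoothing);
#' 2. baseline mean and standard deviation are taken over pre-peak indices
#'    whose value stays below 10% of the maximum;
#' 3. time of arrival is the first index whose value exceeds
#'    `mean + k_sigma * sd` for two consecutive points;
#' 4. the peak is the global maximum;
#' 5. the post-peak minimum is the first interior local minimum after the
#'    peak; if reperfusion never dips before the end of the acquisition, the
#'    final time point is assigned to RPP and the outflow period shortened by
#'    one (with a warning).
#'
#' @param curve A `concentration_curve` (or bare numeric vector).
#' @param k_sigma Arrival threshold in baseline standard deviations
#'   (default 3).
#' @param smooth_width Odd moving-average window in time points (default 3).
#' @return A [bolus_phases].
#' @examples
#' y <- c(0, 0, 0, 1, 2, 3, 2, 1, 1, 1)
#' detect_phases(y, smooth_width = 1)
#' @export
detect_phases <- function(curve, k_sigma = 3, smooth_width = 3L) {
  values <- if (inherits(curve, "concentration_curve")) curve$values else as.numeric(curve)
  n <- length(values)
  if (n < 4L) stop("need at least 4 time points")
  if (!is_odd(smooth_width)) stop("`smooth_width` must be odd")
  y <- moving_average_reflect(values, smooth_width)
  t_peak <- which.max(y)
  ymax <- y[t_peak]
  base_idx <- which(seq_len(n) < t_peak & y < 0.1 * ymax)
  if (t_peak == 1L || ymax <= 0 || length(base_idx) == 0L)
    stop("no bolus detected: curve has no pre-peak baseline below 10% of maximum")
  mu <- mean(y[base_idx])
  sigma <- stats::sd(y[base_idx])
  if (!is.finite(sigma)) sigma <- 0
  if (sigma == 0 && ymax <= mu) stop("no bolus detected: flat curve")
  thr <- mu + k_sigma * sigma
  above <- y > thr
  toa <- NA_integer_
  for (i in seq_len(t_peak - 1L)) {
    if (above[i] && above[min(i + 1L, n)]) { toa <- i; break }
  }
  if (is.na(toa)) stop("no bolus detected: arrival threshold never exceeded before the peak")
  if (toa <= 1L)
    stop("no baseline period: contrast already present at the first time point")
  t_min <- NA_integer_
  if (t_peak + 1L <= n - 1L) {
    for (i in (t_peak + 1L):(n - 1L)) {
      if (y[i] <= y[i - 1L] && y[i] <= y[i + 1L]) { t_min <- i; break }
    }
  }
  if (is.na(t_min)) {
    warning("reperfusion never dips: assigning the final time point to RPP")
    t_min <- n - 1L
  }
  bolus_phases(toa = toa, t_peak = t_peak, t_min = t_min, t_end = n)
}

#' Time indices belonging to a bolus phase interval
#'
#' @param phases A [bolus_phases].
#' @param interval `"BLP"`, `"IFP"`, `"OFP"` or `"RPP"`.
#' @return Ordered integer vector of 1-based time indices. The four member
#'   lists are pairwise disjoint and together cover the whole time axis.
#' @export
interval_members <- function(phases, interval) {
  stopifnot(inherits(phases, "bolus_phases"))
  interval <- match.arg(interval, INTERVALS)
  idx <- phases$t_first:phases$t_end
  idx[phases$interval_of == interval]
}
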