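#' Zero-phase low-pass smoothing of a daily series
#'
#' Smooths the daily counts with a Butterworth low-pass filter applied
#' forward and backward, so the output has zero phase shift and detected
#' change dates stay aligned with the raw calendar.  The cutoff is a fraction
#' of the Nyquist frequency (0.2 keeps slow multi-day trends and attenuates
#' day-to-day jitter).  The filter has unit DC gain: a constant series is
#' returned unchanged, and adding a constant to the input adds the same
#' constant to the output.
#'
#' Edge handling follows the standard filtfilt construction: the series is
#' extended at both ends by odd reflection and the filter is started from its
#' constant-input steady state, so short series are not distorted by
#' zero-state transients.
#'
#' @param series A [daily_series()] (or bare numeric vector).
#' @param cutoff Normalized cutoff in (0, 1), fraction of Nyquist.
#' @param order Butterworth order (default 1).
#' @return A `smoothed_series`: same structure as the input series with real
#'   `values` in place of counts.
#' @export
lowpass_smooth <- function(series, cutoff = 0.2, order = 1L) {
  x <- if (inherits(series, "daily_series")) series$counts else as.numeric(series)
  if (length(x) < 7L) {
    stop("series too short to smooth: need at least 7 days, got ", length(x))
  }
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)")
  bf <- signal::butter(order, cutoff, type = "low")
  y <- .filtfilt_ss(bf$b, bf$a, x)
  .as_smoothed(series, y, cutoff = cutoff, order = order)
}

#' Identity smoother (no filtering)
#'
#' Passes the daily counts through unchanged; useful when derivatives should
#' be computed on the raw series (e.g. hand-checkable fixtures).
#'
#' @param series A [daily_series()] or numeric vector.
#' @return A `smoothed_series` with values equal to the input counts.
#' @export
identity_smooth <- function(series) {
  x <- if (inherits(series, "daily_series")) series$counts else as.numeric(series)
  .as_smoothed(series, x, cutoff = NA_real_, order = 0L)
}

.as_smoothed <- function(series, values, cutoff, order) {
  if (inherits(series, "daily_series")) {
    out <- list(start_date = series$start_date, dates = series$dates,
                values = values)
  } else {
    out <- list(start_date = NA, dates = seq_along(values), values = values)
  }
  structure(c(out, list(cutoff = cutoff, order = order)),
            class = "smoothed_series")
}

# Zero-phase IIR filtering with odd-reflection padding and steady-state
# initial conditions (direct form II transposed).
.filtfilt_ss <- function(b, a, x) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  pad <- max(3L * (n - 1L), 12L)
  pad <- min(pad, length(x) - 1L)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - pad)]
  xp <- c(left, x, right)
  zi <- .lfilter_zi(b, a)
  fwd <- .lfilter(b, a, xp, zi * xp[1])
  rev_in <- rev(fwd)
  bwd <- .lfilter(b, a, rev_in, zi * rev_in[1])
  y <- rev(bwd)
  y[seq(pad + 1L, pad + length(x))]
}

.lfilter <- function(b, a, x, z) {
  n <- length(b)
  y <- numeric(length(x))
  if (n == 1L) return(b[1] * x)
  z <- c(z, 0)
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    for (j in seq_len(n - 1L)) {
      z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    }
    y[i] <- yi
  }
  y
}

# Steady-state filter state for constant input 1 (lfilter_zi construction).
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  if (n == 1L) return(numeric(0))
  a0 <- a[1]
  a <- c(a, rep(0, n - length(a))) / a0
  b <- c(b, rep(0, n - length(b))) / a0
  m <- n - 1L
  A <- matrix(0, m, m)
  A[, 1] <- -a[-1]
  if (m > 1L) A[seq_len(m - 1L), 2L:m] <- diag(1, m - 1L)
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - A, B)
}

#' Velocity and acceleration of a smoothed series
#'
#' Velocity is the day-over-day first difference `v[t] = S[t] - S[t-1]` and
#' acceleration its difference `a[t] = v[t] - v[t-1]`; both are `NA` on the
#' days where they are undefined (the first day for velocity, the first two
#' for acceleration).  Alternative derivative definitions are available:
#' `"log"` differences `log(S[t]) - log(S[t-1])` (counts are offset by 1 to
#' keep zero days finite) and the `"ratio"` form `S[t]/S[t-1] - 1`.
#'
#' @param smoothed A `smoothed_series` (or [daily_series()], used as-is).
#' @param method Derivative definition: `"difference"` (default), `"log"`,
#'   or `"ratio"`.
#' @return A `derivative_series`: list with `dates`, `velocity`,
#'   `acceleration`.
#' @export
compute_derivatives <- function(smoothed,
                                method = c("difference", "log", "ratio")) {
  method <- match.arg(method)
  if (inherits(smoothed, "daily_series")) smoothed <- identity_smooth(smoothed)
  s <- smoothed$values
  if (length(s) < 3L) stop("need at least 3 days to compute acceleration")
  base <- switch(method,
    difference = s,
    log = log(s + 1),
    ratio = s
  )
  v <- c(NA_real_, diff(base))
  if (method == "ratio") {
    prev <- base[-length(base)]
    v <- c(NA_real_, ifelse(prev > 0, base[-1] / prev - 1, NA_real_))
  }
  a <- c(NA_real_, diff(v))
  structure(list(dates = smoothed$dates, velocity = v, acceleration = a,
                 method = method),
            class = "derivative_series")
}

#' Learn detection thresholds from the ground-truth date
#'
#' Takes the velocity and acceleration on the ground-truth (GT) anchor date
#' (the day the stream's first confirmed case was announced) and converts
#' them to detection thresholds by the floor rules: the velocity threshold is
#' `floor(v_gt) + 1` and the acceleration threshold `floor(a_gt)`.  Once
#' learned the pair is fixed for the whole study window.
#'
#' @param deriv A `derivative_series`.
#' @param gt_date The anchor date; must have defined velocity and
#'   acceleration (at least two days after the series start).
#' @return A `threshold_pair`: list with `v_thresh`, `a_thresh`, `gt_date`,
#'   `v_gt`, `a_gt`.
#' @export
learn_thresholds <- function(deriv, gt_date) {
  gt_date <- .align_date(gt_date, deriv$dates)
  i <- match(TRUE, deriv$dates == gt_date)
  if (is.na(i)) stop("gt_date is outside the series")
  if (i < 3L || is.na(deriv$velocity[i]) || is.na(deriv$acceleration[i])) {
    stop("gt_date must be at least two days after the series start so that ",
         "velocity and acceleration are defined")
  }
  v_gt <- deriv$velocity[i]
  a_gt <- deriv$acceleration[i]
  if (v_gt <= 0) {
    warning("velocity at gt_date is not positive; the detection condition ",
            "0 < velocity < v_thresh may never hold")
  }
  structure(list(v_thresh = floor(v_gt) + 1, a_thresh = floor(a_gt),
                 gt_date = gt_date, v_gt = v_gt, a_gt = a_gt),
            class = "threshold_pair")
}

.align_date <- function(d, dates) {
  if (inherits(dates, "Date")) as.Date(d) else as.numeric(d)
}

#' Detect topic-phase start dates
#'
#' Returns the ground-truth date plus every later date where velocity is
#' still small but acceleration has become substantial — strictly
#' `0 < velocity < v_thresh` and `acceleration > a_thresh`.  Runs of
#' consecutive qualifying days are collapsed to their earliest day (one surge
#' starts one phase).
#'
#' @param deriv A `derivative_series`.
#' @param thr A `threshold_pair` from [learn_thresholds()].
#' @param window Optional length-2 date vector restricting the search.
#' @return Sorted vector of phase-start dates, beginning with the GT date.
#' @export
detect_phase_starts <- function(deriv, thr, window = NULL) {
  stopifnot(inherits(thr, "threshold_pair"))
  v <- deriv$velocity
  a <- deriv$acceleration
  d <- deriv$dates
  ok <- !is.na(v) & !is.na(a) &
    v > 0 & v < thr$v_thresh & a > thr$a_thresh & d > thr$gt_date
  if (!is.null(window)) ok <- ok & d >= window[1] & d <= window[2]
  idx <- which(ok)
  # collapse runs of consecutive qualifying days to the earliest day
  firsts <- idx[c(TRUE, diff(idx) > 1L)]
  sort(c(thr$gt_date, d[firsts]))
}

#' Partition the study window into phases
#'
#' Phase 0 spans from the first day of the window to the day before the first
#' detected start; each later phase runs from its start to the day before the
#' next one, and the last phase ends on the window's final day.  If the first
#' start coincides with the window start, phase 0 is empty and omitted (ids
#' still begin at 0).
#'
#' @param starts Sorted phase-start dates, all inside the window.
#' @param window Length-2 date vector (first day, last day).
#' @return A `phase_segmentation`: data.frame with `phase_id`, `start`, `end`.
#' @export
segment_phases <- function(starts, window) {
  window <- if (inherits(window, "Date") || inherits(starts, "Date")) {
    as.Date(window)
  } else as.numeric(window)
  starts <- sort(unique(starts))
  if (length(starts) && (min(starts) < window[1] || max(starts) > window[2])) {
    stop("phase starts must lie inside the window")
  }
  bounds <- unique(c(window[1], starts))
  ends <- c(bounds[-1] - 1L, window[2])
  if (!inherits(ends, class(bounds)[1]) && inherits(bounds, "Date")) {
    ends <- as.Date(ends, origin = "1970-01-01")
  }
  seg <- data.frame(phase_id = seq_along(bounds) - 1L,
                    start = bounds, end = ends)
  class(seg) <- c("phase_segmentation", "data.frame")
  attr(seg, "window") <- window
  seg
}

#' End-to-end phase detection on a daily series
#'
#' Convenience wrapper: smooth (unless `smooth = FALSE`), differentiate,
#' learn thresholds at `gt_date`, detect starts, and segment the window.
#'
#' @param series A [daily_series()].
#' @param gt_date Ground-truth anchor date (first confirmed case).
#' @param cutoff Low-pass cutoff, fraction of Nyquist.
#' @param smooth If `FALSE`, derivatives are taken on the raw counts.
#' @param method Derivative definition, see [compute_derivatives()].
#' @return A list with `segmentation`, `thresholds`, `starts`, `deriv`,
#'   `smoothed`.
#' @export
detect_phases <- function(series, gt_date, cutoff = 0.2, smooth = TRUE,
                          method = "difference") {
  sm <- if (smooth) lowpass_smooth(series, cutoff = cutoff) else identity_smooth(series)
  deriv <- compute_derivatives(sm, method = method)
  thr <- learn_thresholds(deriv, gt_date)
  window <- range(series$dates)
  starts <- detect_phase_starts(deriv, thr, window = window)
  list(segmentation = segment_phases(starts, window), thresholds = thr,
       starts = starts, deriv = deriv, smoothed = sm)
}
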