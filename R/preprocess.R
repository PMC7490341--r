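#' Zero sub-threshold activity
#'
#' Values strictly below `lambda` are set to 0; values equal to or above it
#' are unchanged. Applying the operation twice equals applying it once.
#'
#' @param series Nonnegative numeric series (`NA` allowed).
#' @param lambda Threshold in activity units.
#' @return Series of the same length.
#' @export
threshold_activity <- function(series, lambda = 0.005) {
  if (any(series < 0, na.rm = TRUE))
    stop("activity series must be nonnegative")
  stopifnot(lambda >= 0)
  series[!is.na(series) & series < lambda] <- 0
  series
}

#' Band-pass filter an activity segment
#'
#' Digital Butterworth band-pass (order and cutoffs from `params`), applied
#' zero-phase (forward-backward) by default. Cutoffs are fractions of the
#' Nyquist frequency (0.5 cycles/min at 1-min binning). Output length
#' equals input length; output may be negative.
#'
#' @param series Numeric series, length must exceed `3 * filter_order`.
#' @param params An [rdi_params] object.
#' @return Filtered series.
#' @export
bandpass_filter <- function(series, params = rdi_params()) {
  if (length(series) <= 3 * params$filter_order)
    stop("segment_too_short_for_filter")
  sos <- butter_bandpass_sos(params$filter_order, params$f_low, params$f_high)
  sos_filtfilt(sos, series, zero_phase = params$zero_phase)
}

#' Centered moving average with shrinking edge windows
#'
#' Minute `t` averages the window `[t - floor(w/2), t + ceiling(w/2) - 1]`
#' intersected with the series, so endpoints average fewer samples but stay
#' unbiased in level (no padding).
#'
#' @param series Numeric series.
#' @param window Window length (minutes), `>= 1`.
#' @return Smoothed series of the same length.
#' @export
moving_average <- function(series, window = 60L) {
  n <- length(series)
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window longer than series")
  if (window == 1) return(series)
  half_lo <- window %/% 2
  half_hi <- window - half_lo - 1L
  cs <- cumsum(c(0, series))
  t <- seq_len(n)
  lo <- pmax(t - half_lo, 1L)
  hi <- pmin(t + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Normalize a series to peak activity
#'
#' Divides by the maximum so the peak equals exactly 1. An all-zero series
#' is returned unchanged with a warning.
#'
#' @param series Nonnegative numeric series.
#' @return Normalized series.
#' @export
normalize_to_peak <- function(series) {
  if (any(series < 0, na.rm = TRUE)) stop("series must be nonnegative")
  mx <- max(series, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) {
    warning("all-zero series: nothing to normalize")
    return(series)
  }
  series / mx
}

#' Find the least active consecutive hour of a day
#'
#' Scans all 60-min contiguous windows of the raw (unfiltered,
#' unthresholded) 1440-min day and returns the one with the lowest mean
#' activity; ties are broken by the earliest start.
#'
#' @param day_minutes Complete 1440-min day vector (minute 1 = lights-on).
#' @param window Window length in minutes.
#' @return List of class `least_active_hour`: `start_minute` (0-based
#'   offset from lights-on), `mean_activity`, `segment`.
#' @export
find_least_active_hour <- function(day_minutes, window = 60L) {
  n <- length(day_minutes)
  if (anyNA(day_minutes)) stop("day is incomplete (missing minutes)")
  if (n < window) stop("day shorter than the search window")
  cs <- cumsum(c(0, day_minutes))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  # earliest tie at floating-point resolution
  tol <- 1e-9 * max(1, abs(min(means)))
  s <- which(means <= min(means) + tol)[1]
  structure(list(start_minute = s - 1L,
                 mean_activity = mean(day_minutes[s:(s + window - 1)]),
                 segment = day_minutes[s:(s + window - 1)]),
            class = "least_active_hour")
}
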