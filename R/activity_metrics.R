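#' Weekly day- or night-phase activity
#'
#' Mean of all 1-min bins of the given phase across a week's valid days,
#' per cage.
#'
#' @param days An `analysis_days` object (or list of them), exclusions
#'   applied.
#' @param phase `"day"` (light) or `"night"` (dark).
#' @param meta `cage_metadata`.
#' @param week_range Analysis window in weeks of age.
#' @return Weekly values as from [weekly_aggregate()], metric
#'   `activity_day` or `activity_night`.
#' @export
weekly_activity <- function(days, phase = c("day", "night"), meta,
                            week_range = c(7L, 24L)) {
  phase <- match.arg(phase)
  if (inherits(days, "analysis_days")) days <- list(days)
  daily <- do.call(rbind, lapply(days, function(d) {
    keep <- which(d$valid)
    cols <- if (phase == "day") 1:d$day_len else (d$day_len + 1):1440
    data.frame(cage_id = d$cage_id, date = d$date[keep],
               metric = paste0("activity_", phase),
               value = if (length(keep))
                 rowMeans(d$minutes[keep, cols, drop = FALSE]) else numeric(0),
               stringsAsFactors = FALSE)
  }))
  weekly_aggregate(daily, meta, week_range)
}

#' Average 24 h activity profile per group
#'
#' Each valid cage-day is smoothed with a centered 60-min moving average
#' and normalized to peak activity (maximum = 1), then profiles are
#' averaged across all days and cages of each group. Normalizing before
#' averaging removes between-cage amplitude so the group profile reflects
#' shape only.
#'
#' @param days_list List of `analysis_days` objects (one per cage).
#' @param groups Named character vector mapping cage id to group label.
#' @param smooth_window Moving-average window in minutes.
#' @return Named list per group, each with `values` (length 1440, minute 1
#'   = lights-on), `n_cages`, `n_days`.
#' @export
daily_profile <- function(days_list, groups, smooth_window = 60L) {
  if (inherits(days_list, "analysis_days")) days_list <- list(days_list)
  acc <- list()
  for (d in days_list) {
    g <- groups[[d$cage_id]]
    if (is.null(g) || is.na(g)) next
    for (i in which(d$valid)) {
      x <- moving_average(d$minutes[i, ], smooth_window)
      if (max(x) > 0) x <- x / max(x)
      if (is.null(acc[[g]]))
        acc[[g]] <- list(sum = numeric(1440), n_days = 0L, cages = character(0))
      acc[[g]]$sum <- acc[[g]]$sum + x
      acc[[g]]$n_days <- acc[[g]]$n_days + 1L
      acc[[g]]$cages <- union(acc[[g]]$cages, d$cage_id)
    }
  }
  lapply(acc, function(a) {
    if (a$n_days == 0L) warning("group has no valid days")
    list(values = if (a$n_days) a$sum / a$n_days else a$sum,
         n_cages = length(a$cages), n_days = a$n_days)
  })
}

#' Late-stage decline slope per cage
#'
#' Ordinary least-squares slope of a weekly metric against week of age,
#' restricted to a week range (16-24 by default) and to weeks with two
#' mice in the cage.
#'
#' @param weekly Weekly values (one metric) as from [weekly_aggregate()].
#' @param week_range Inclusive week window for the fit.
#' @param two_mouse_weeks Optional `data.frame` with `cage_id`, `week`,
#'   `n_mice`; weeks with `n_mice < 2` are excluded from the fit. `NULL`
#'   keeps all weeks.
#' @return `data.frame` per cage: `slope` (units/week), `intercept`,
#'   `n_weeks`, `reason` (`""`, or `"insufficient_weeks"` with `NA` slope).
#' @export
decline_slope <- function(weekly, week_range = c(16L, 24L),
                          two_mouse_weeks = NULL) {
  w <- weekly[!is.na(weekly$value) &
                weekly$week >= week_range[1] & weekly$week <= week_range[2], ]
  if (!is.null(two_mouse_weeks)) {
    key <- paste(w$cage_id, w$week)
    ok2 <- paste(two_mouse_weeks$cage_id, two_mouse_weeks$week)[
      two_mouse_weeks$n_mice >= 2]
    w <- w[key %in% ok2, ]
  }
  out <- lapply(split(w, w$cage_id), function(d) {
    if (nrow(d) < 2 || length(unique(d$week)) < 2)
      return(data.frame(cage_id = d$cage_id[1], slope = NA_real_,
                        intercept = NA_real_, n_weeks = nrow(d),
                        reason = "insufficient_weeks",
                        stringsAsFactors = FALSE))
    fit <- lm(value ~ week, data = d)
    data.frame(cage_id = d$cage_id[1], slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), n_weeks = nrow(d),
               reason = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lag maximizing the cross-correlation of two longitudinal curves
#'
#' Both curves are compared on a common weekly grid. For each candidate
#' lag, the Pearson correlation between the overlapping parts of `a[t]`
#' and `b[t - lag]` is computed; the returned lag maximizes it, ties going
#' to the smallest `|lag|` (then to the negative lag). A positive lag
#' means the second curve anticipates (leads) the first.
#'
#' @param curve_a,curve_b Numeric vectors on the same weekly grid.
#' @param max_lag Largest lag magnitude to scan (must leave at least 3
#'   overlapping points).
#' @return List of class `lag_result`: `lag`, `correlation`, and the full
#'   `by_lag` table.
#' @export
curve_lag <- function(curve_a, curve_b, max_lag = 3L) {
  stopifnot(length(curve_a) == length(curve_b))
  n <- length(curve_a)
  if (max_lag >= n - 2) stop("max_lag too large for curve length")
  if (sd(curve_a) == 0 || sd(curve_b) == 0) stop("zero_variance_curve")
  lags <- seq.int(-max_lag, max_lag)
  cc <- vapply(lags, function(l) {
    ta <- seq.int(max(1, 1 + l), min(n, n + l))  # indices of a; b index = t - l
    if (length(ta) < 3) return(NA_real_)
    a <- curve_a[ta]; b <- curve_b[ta - l]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  ord <- order(-cc, abs(lags), lags)
  best <- ord[1]
  structure(list(lag = lags[best], correlation = cc[best],
                 by_lag = data.frame(lag = lags, correlation = cc)),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("curve lag: %+d week(s) (max cross-correlation %.3f)\n",
              x$lag, x$correlation))
  invisible(x)
}
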