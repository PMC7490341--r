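pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Sample entropy of a numeric series
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates
#' whose Chebyshev distance is at most `r`, and A the same for length
#' `m + 1`; self-matches are excluded and both counts use the first
#' `N - m` templates. The tolerance is `r_frac` times the SD, using the
#' population (1/N) standard deviation of the series.
#'
#' Degenerate cases: a zero-variance (constant) series has no irregularity
#' and returns exactly 0 with `degenerate = TRUE`; when no template pairs
#' match (`B = 0`) or no extended pairs match (`A = 0`) on a non-constant
#' series, the entropy is undefined and `value` is `NA` with
#' `degenerate = TRUE`.
#'
#' @param x Numeric series of length at least `m + 2`.
#' @param m Embedding dimension.
#' @param r_frac Tolerance as a fraction of the series SD.
#' @return List with `value`, `A`, `B`, `r`, `n`, `degenerate`.
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(runif(120))$value
sample_entropy <- function(x, m = 2L, r_frac = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x)) stop("series contains missing values")
  if (n < m + 2) stop("series_too_short")
  s <- pop_sd(x)
  if (s == 0)
    return(list(value = 0, A = NA_real_, B = NA_real_, r = 0, n = n,
                degenerate = TRUE))
  r <- r_frac * s
  cnt <- .sampen_counts(x, as.integer(m), r)
  if (cnt$B == 0 || cnt$A == 0)
    return(list(value = NA_real_, A = cnt$A, B = cnt$B, r = r, n = n,
                degenerate = TRUE))
  list(value = -log(cnt$A / cnt$B), A = cnt$A, B = cnt$B, r = r, n = n,
       degenerate = FALSE)
}

rdi_result_row <- function(cage_id, date, variant, se) {
  data.frame(cage_id = cage_id, date = date, variant = variant,
             value = se$value, n_samples = se$n,
             degenerate = se$degenerate, stringsAsFactors = FALSE)
}

#' Regularity Disruption Index of one activity segment
#'
#' The RDI pipeline: sub-threshold activity is zeroed, the segment is
#' band-pass filtered, and the sample entropy of the result is taken. High
#' RDI indicates fragmented, irregular minute-to-minute activity; a segment
#' in which all minutes carry similar activity gives 0. Multiplying the
#' activity by a positive scalar leaves RDI unchanged (the entropy
#' tolerance scales with the SD).
#'
#' @param segment Complete nonnegative minute series (e.g. 720 minutes of
#'   one light phase, or a 60-min window).
#' @param params An [rdi_params] object.
#' @param variant Label stored with the result (`"day"`, `"night"`,
#'   `"least_active_hour"`, ...).
#' @param cage_id,date Identifiers stored with the result.
#' @param filter Apply the band-pass stage (disabled internally when the
#'   caller has already filtered a longer series).
#' @return One-row `data.frame`: `cage_id`, `date`, `variant`, `value`,
#'   `n_samples`, `degenerate`.
#' @export
#' @examples
#' compute_rdi(rep(0.5, 720))$value  # constant activity -> 0
compute_rdi <- function(segment, params = rdi_params(), variant = "day",
                        cage_id = NA_character_, date = as.Date(NA),
                        filter = TRUE) {
  if (anyNA(segment)) stop("segment is incomplete (missing minutes)")
  if (length(unique(segment)) == 1L) {
    # constant activity: no irregularity by definition; skip the pipeline
    # so filter round-off cannot manufacture spurious entropy
    se <- list(value = 0, n = length(segment), degenerate = TRUE)
    return(rdi_result_row(cage_id, date, variant, se))
  }
  x <- threshold_activity(segment, params$lambda)
  if (filter) x <- bandpass_filter(x, params)
  if (pop_sd(x) <= 1e-12 * max(1, max(abs(segment)))) {
    se <- list(value = 0, n = length(segment), degenerate = TRUE)
    return(rdi_result_row(cage_id, date, variant, se))
  }
  se <- sample_entropy(x, params$m, params$r_frac)
  rdi_result_row(cage_id, date, variant, se)
}

## Shared preprocessing for 60-min-window variants: threshold (pointwise,
## so window-local and day-level agree), then one day-level band-pass. A
## band-pass whose lowest passband period is 2000 samples is not
## meaningful on an isolated 60-sample window.
prep_day_for_windows <- function(day_minutes, params) {
  bandpass_filter(threshold_activity(day_minutes, params$lambda), params)
}

window_sampen <- function(xw, params) {
  if (pop_sd(xw) <= 1e-12 * max(1, max(abs(xw))))
    list(value = 0, n = length(xw), degenerate = TRUE)
  else sample_entropy(xw, params$m, params$r_frac)
}

#' Moving RDI across a day
#'
#' For each minute `t` with a complete centered window
#' `[t - w/2, t + w/2 - 1]`, the RDI of that window; the first and last
#' `w/2` minutes are `NA`. The day series is thresholded and band-pass
#' filtered once; the entropy tolerance is window-local
#' (`r_frac * SD(window)`). For display the curve is conventionally
#' smoothed downstream with a further 60-min [moving_average()].
#'
#' @param day_minutes Complete 1440-min day vector.
#' @param params An [rdi_params] object.
#' @return Numeric vector of length 1440 with `NA` at the edges.
#' @export
moving_rdi <- function(day_minutes, params = rdi_params()) {
  if (anyNA(day_minutes)) stop("day is incomplete (missing minutes)")
  n <- length(day_minutes)
  w <- params$window_w
  half_lo <- w %/% 2
  filt <- prep_day_for_windows(day_minutes, params)
  out <- rep(NA_real_, n)
  for (t in (half_lo + 1):(n - (w - half_lo - 1))) {
    out[t] <- window_sampen(filt[(t - half_lo):(t + w - half_lo - 1)],
                            params)$value
  }
  out
}

#' Daily RDI for the day, night and least-active-hour variants
#'
#' For every valid analysis day, computes RDI of the light-phase segment
#' (`N = day_len`, 720 by default), the dark-phase segment (`N = 720`), and
#' the least active consecutive hour (`N = 60`; the hour is located on the
#' raw day, the entropy is taken on the day-level filtered series at that
#' window). With `filter_scope = "segment"` (default) the two 720-min
#' phases are filtered independently; with `"full_day"` the 1440-min day is
#' filtered once and then split.
#'
#' @param days An `analysis_days` object (exclusions already applied).
#' @param params An [rdi_params] object.
#' @return `data.frame` with one row per (date, variant): `cage_id`,
#'   `date`, `variant`, `value`, `n_samples`, `degenerate`.
#' @export
rdi_by_variant <- function(days, params = rdi_params()) {
  keep <- which(days$valid)
  dl <- days$day_len
  out <- vector("list", 3L * length(keep))
  k <- 0L
  for (i in keep) {
    full <- days$minutes[i, ]
    filt <- prep_day_for_windows(full, params)
    if (params$filter_scope == "segment") {
      day_seg <- full[1:dl]
      night_seg <- full[(dl + 1):1440]
      rd <- compute_rdi(day_seg, params, "day", days$cage_id, days$date[i])
      rn <- compute_rdi(night_seg, params, "night", days$cage_id, days$date[i])
    } else {
      sed <- window_sampen(filt[1:dl], params)
      sen <- window_sampen(filt[(dl + 1):1440], params)
      rd <- rdi_result_row(days$cage_id, days$date[i], "day", sed)
      rn <- rdi_result_row(days$cage_id, days$date[i], "night", sen)
    }
    lah <- find_least_active_hour(full, params$window_w)
    widx <- (lah$start_minute + 1):(lah$start_minute + params$window_w)
    sel <- window_sampen(filt[widx], params)
    rl <- rdi_result_row(days$cage_id, days$date[i], "least_active_hour", sel)
    out[[k <- k + 1L]] <- rd
    out[[k <- k + 1L]] <- rn
    out[[k <- k + 1L]] <- rl
  }
  if (!k) return(data.frame(cage_id = character(), date = as.Date(character()),
                            variant = character(), value = numeric(),
                            n_samples = integer(), degenerate = logical()))
  do.call(rbind, out[seq_len(k)])
}

#' Weekly average RDI
#'
#' Weekly means per cage and variant. Degenerate constant-series zeros are
#' genuine "perfectly regular" observations and enter the mean; undefined
#' entropies (`NA`) are excluded.
#'
#' @param results Output of [rdi_by_variant()] (possibly several cages
#'   row-bound).
#' @param meta `cage_metadata`.
#' @param week_range Analysis window in weeks of age.
#' @return Weekly values as from [weekly_aggregate()], with metric names
#'   `rdi_day`, `rdi_night`, `rdi_least_active_hour`.
#' @export
weekly_rdi <- function(results, meta, week_range = c(7L, 24L)) {
  daily <- data.frame(cage_id = results$cage_id, date = results$date,
                      metric = paste0("rdi_", results$variant),
                      value = results$value, stringsAsFactors = FALSE)
  weekly_aggregate(daily, meta, week_range)
}
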