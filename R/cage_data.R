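#' Minute-binned activity trace for one cage
#'
#' @param cage_id Cage identifier.
#' @param start POSIXct (UTC) timestamp of the first minute bin.
#' @param values Numeric vector of nonnegative per-minute activity; `NA`
#'   marks a missing minute.
#' @return An object of class `activity_trace`.
#' @export
activity_trace <- function(cage_id, start, values) {
  stopifnot(is.character(cage_id), length(cage_id) == 1,
            inherits(start, "POSIXct"), length(start) == 1)
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE))
    stop("activity values must be nonnegative")
  structure(list(cage_id = cage_id, start = start, values = values),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("activity_trace: cage %s, %d minutes from %s UTC (%d missing)\n",
              x$cage_id, length(x$values), format(x$start, "%Y-%m-%d %H:%M"),
              sum(is.na(x$values))))
  invisible(x)
}

parse_minute_ts <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  as.POSIXct(trunc(ts, "mins"))
}

#' Read minute-binned activity from CSV
#'
#' Expects long format with one row per cage-minute. Minutes absent from the
#' file inside a cage's span become explicitly missing (`NA`) bins.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping the roles `cage_id`,
#'   `timestamp` (ISO-8601, minute precision) and `activity` to column names.
#' @return Named list of [activity_trace] objects, one per cage.
#' @export
read_activity_csv <- function(path,
                              schema = c(cage_id = "cage_id",
                                         timestamp = "timestamp",
                                         activity = "activity")) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema[c("cage_id", "timestamp", "activity")]),
                          names(df))
  if (length(missing_cols))
    stop("activity CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  cage <- as.character(df[[schema[["cage_id"]]]])
  ts <- parse_minute_ts(df[[schema[["timestamp"]]]])
  val <- suppressWarnings(as.numeric(df[[schema[["activity"]]]]))
  bad_ts <- which(is.na(ts))
  bad_val <- which(is.na(val) & !is.na(df[[schema[["activity"]]]]))
  if (length(bad_ts) || length(bad_val))
    warning(sprintf("%d unparseable timestamp row(s), %d unparseable value row(s) dropped",
                    length(bad_ts), length(bad_val)))
  neg <- which(val < 0)
  if (length(neg))
    stop(sprintf("negative activity value at data row %d (cage %s)",
                 neg[1], cage[neg[1]]))
  keep <- !is.na(ts) & !is.na(val)
  cage <- cage[keep]; ts <- ts[keep]; val <- val[keep]
  out <- lapply(split(seq_along(cage), cage), function(idx) {
    o <- idx[order(ts[idx])]
    tt <- ts[o]; vv <- val[o]
    if (anyDuplicated(tt)) {
      warning("duplicate minute timestamps; keeping first occurrence")
      first <- !duplicated(tt)
      tt <- tt[first]; vv <- vv[first]
    }
    grid <- seq(tt[1], tt[length(tt)], by = 60)
    full <- rep(NA_real_, length(grid))
    full[match(as.numeric(tt), as.numeric(grid))] <- vv
    activity_trace(cage[idx[1]], tt[1], full)
  })
  out[order(names(out))]
}

#' Cage metadata table
#'
#' @param path CSV with columns `cage_id`, `genotype` (WT/TG), `sex` (M/F),
#'   `cohort`, `entry_date` (date the cage entered the rack, at age 7
#'   weeks), and optional per-mouse `endpoint_date` columns (blank = none).
#' @return A `data.frame` of class `cage_metadata` with `entry_date` and
#'   endpoint columns parsed as `Date`.
#' @export
read_metadata_csv <- function(path) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cage_id", "genotype", "sex", "cohort", "entry_date")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$genotype %in% c("WT", "TG")))
    stop("genotype must be WT or TG")
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be M or F")
  df$entry_date <- as.Date(df$entry_date)
  if (!"n_mice" %in% names(df)) df$n_mice <- 2L
  if ("endpoint_date" %in% names(df)) {
    df$endpoint_date[df$endpoint_date %in% c("", "NA")] <- NA
    df$endpoint_date <- as.Date(df$endpoint_date)
  } else df$endpoint_date <- as.Date(NA)
  class(df) <- c("cage_metadata", "data.frame")
  df
}

#' Study calendar: light schedule and dated events
#'
#' @param lights_on,lights_off Times of day, `"HH:MM"`. Defaults give the
#'   standard 12 h light phase 07:00-19:00.
#' @param cage_change_dates Named list (per cage id) of `Date` vectors; the
#'   name `"all"` applies to every cage.
#' @param procedure_dates `Date` vector of in-room procedure days (grid or
#'   grip tests, weighing).
#' @return Object of class `study_calendar`.
#' @export
study_calendar <- function(lights_on = "07:00", lights_off = "19:00",
                           cage_change_dates = list(),
                           procedure_dates = as.Date(character())) {
  if (identical(lights_on, lights_off))
    stop("lights_on and lights_off must differ")
  cage_change_dates <- lapply(cage_change_dates, as.Date)
  structure(list(lights_on = lights_on, lights_off = lights_off,
                 cage_change_dates = cage_change_dates,
                 procedure_dates = as.Date(procedure_dates)),
            class = "study_calendar")
}

#' Read a study calendar from YAML
#'
#' Expected keys: `lights_on`, `lights_off` (HH:MM strings), `cage_change`
#' (mapping of cage id, or `all`, to date lists), `procedures` (date list).
#'
#' @param path YAML file path.
#' @return A [study_calendar] object.
#' @export
read_calendar_yaml <- function(path) {
  stopifnot(file.exists(path))
  y <- yaml::read_yaml(path)
  study_calendar(lights_on = if (is.null(y$lights_on)) "07:00" else y$lights_on,
                 lights_off = if (is.null(y$lights_off)) "19:00" else y$lights_off,
                 cage_change_dates = if (is.null(y$cage_change)) list() else
                   lapply(y$cage_change, as.Date),
                 procedure_dates = if (is.null(y$procedures))
                   as.Date(character()) else as.Date(unlist(y$procedures)))
}

minute_of_day <- function(hhmm) {
  p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

cage_change_for <- function(cal, cage_id) {
  d <- cal$cage_change_dates
  as.Date(c(if (!is.null(d[[cage_id]])) d[[cage_id]],
            if (!is.null(d[["all"]])) d[["all"]]))
}

#' Split a trace into analysis days
#'
#' An analysis day runs lights-on to the next lights-on, so minute 0 of
#' every per-day vector is lights-on. Under the default 07:00/19:00
#' schedule the light ("day") phase is minutes 1-720 and the dark ("night")
#' phase minutes 721-1440. Days containing any missing minute are flagged
#' invalid with reason `"incomplete_day"`; partial days at the trace
#' boundaries are dropped.
#'
#' @param trace An [activity_trace].
#' @param cal A [study_calendar].
#' @return Object of class `analysis_days`: list with `cage_id`, `date`
#'   (calendar date of each day's lights-on), `minutes` (days x 1440
#'   matrix), `day_len` (light-phase length in minutes), `valid`, `reason`.
#' @export
split_analysis_days <- function(trace, cal = study_calendar()) {
  on_min <- minute_of_day(cal$lights_on)
  off_min <- minute_of_day(cal$lights_off)
  day_len <- (off_min - on_min) %% 1440
  tod <- (as.integer(trace$start) %/% 60) %% 1440  # minute of day, UTC
  offset <- (on_min - tod) %% 1440                 # minutes until first lights-on
  n <- length(trace$values)
  n_days <- (n - offset) %/% 1440
  empty <- structure(list(cage_id = trace$cage_id, date = as.Date(character()),
                          minutes = matrix(numeric(0), 0, 1440),
                          day_len = day_len, valid = logical(0),
                          reason = character(0)),
                     class = "analysis_days")
  if (n_days < 1) {
    warning("trace shorter than one full lights-on to lights-on cycle")
    return(empty)
  }
  idx <- offset + seq_len(n_days * 1440)
  m <- matrix(trace$values[idx], nrow = n_days, ncol = 1440, byrow = TRUE)
  first_on <- trace$start + offset * 60
  dates <- as.Date(seq(first_on, by = "1 day", length.out = n_days), tz = "UTC")
  incomplete <- apply(m, 1, anyNA)
  structure(list(cage_id = trace$cage_id, date = dates, minutes = m,
                 day_len = day_len, valid = !incomplete,
                 reason = ifelse(incomplete, "incomplete_day", "")),
            class = "analysis_days")
}

#' @export
print.analysis_days <- function(x, ...) {
  cat(sprintf("analysis_days: cage %s, %d day(s), %d valid\n",
              x$cage_id, length(x$date), sum(x$valid)))
  invisible(x)
}

#' Apply study-level exclusion rules
#'
#' Removes cage-change days and, by default, all days of any cage in which
#' a mouse died before its scheduled endpoint (whole-cage exclusion; set
#' `exclude_dead_cage = FALSE` to instead truncate the cage at the death
#' date). Each exclusion carries a machine-readable reason.
#'
#' @param days An `analysis_days` object.
#' @param cal A [study_calendar].
#' @param meta Optional `cage_metadata` row(s) for this cage (used for
#'   death handling via `endpoint_date`).
#' @param exclude_dead_cage Whole-cage exclusion on unscheduled death.
#' @return The `analysis_days` object with updated `valid`/`reason`.
#' @export
apply_exclusions <- function(days, cal, meta = NULL, exclude_dead_cage = TRUE) {
  cc <- cage_change_for(cal, days$cage_id)
  hit <- days$valid & (days$date %in% cc)
  days$valid[hit] <- FALSE
  days$reason[hit] <- "cage_change"
  if (!is.null(meta)) {
    row <- meta[meta$cage_id == days$cage_id, , drop = FALSE]
    if (nrow(row) && !is.na(row$endpoint_date[1])) {
      if (exclude_dead_cage) {
        days$reason[days$valid] <- "death_in_cage"
        days$valid[] <- FALSE
      } else {
        late <- days$valid & days$date >= row$endpoint_date[1]
        days$valid[late] <- FALSE
        days$reason[late] <- "after_death"
      }
    }
  }
  days
}

#' Map dates to week of age
#'
#' Weeks are 7-day blocks anchored at the cage's rack-entry date, when
#' animals are `entry_age_weeks` old (7 by default).
#'
#' @param dates `Date` vector.
#' @param entry_date Rack-entry date for the cage.
#' @param entry_age_weeks Age in weeks at entry.
#' @return Integer weeks of age.
#' @export
week_of_age <- function(dates, entry_date, entry_age_weeks = 7L) {
  as.integer(entry_age_weeks + floor(as.numeric(dates - as.Date(entry_date)) / 7))
}

#' Aggregate per-day metric values into weekly means
#'
#' @param daily `data.frame` with columns `cage_id`, `date`, `metric`,
#'   `value`.
#' @param meta `cage_metadata` (for `entry_date`).
#' @param week_range Analysis window in weeks of age; values outside it are
#'   kept but flagged `out_of_range`.
#' @return `data.frame` with `cage_id`, `week`, `metric`, `value` (mean of
#'   available days; `NA` when a week has none), `n_days`, `out_of_range`.
#' @export
weekly_aggregate <- function(daily, meta, week_range = c(7L, 24L)) {
  stopifnot(all(c("cage_id", "date", "metric", "value") %in% names(daily)))
  entry <- meta$entry_date[match(daily$cage_id, meta$cage_id)]
  if (anyNA(entry)) stop("cage(s) missing from metadata: ",
                         paste(unique(daily$cage_id[is.na(entry)]), collapse = ", "))
  daily$week <- week_of_age(daily$date, entry)
  key <- interaction(daily$cage_id, daily$week, daily$metric, drop = TRUE)
  agg <- lapply(split(daily, key), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(cage_id = d$cage_id[1], week = d$week[1], metric = d$metric[1],
               value = if (length(v)) mean(v) else NA_real_,
               n_days = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out$out_of_range <- out$week < week_range[1] | out$week > week_range[2]
  out[order(out$metric, out$cage_id, out$week), ]
}

#' Stratify analysis days by day type
#'
#' Every valid day falls in exactly one stratum: `cage_change` (takes
#' precedence), `weekend` (Saturday/Sunday), or `weekday` (working days,
#' when husbandry or test procedures may occur).
#'
#' @param days An `analysis_days` object.
#' @param cal A [study_calendar].
#' @return Character vector, one stratum per day (`NA` for invalid days).
#' @export
stratify_by_day_type <- function(days, cal) {
  cc <- cage_change_for(cal, days$cage_id)
  wd <- format(days$date, "%u")  # 1 = Monday ... 7 = Sunday
  out <- ifelse(days$date %in% cc, "cage_change",
                ifelse(wd %in% c("6", "7"), "weekend", "weekday"))
  out[!days$valid] <- NA_character_
  out
}
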