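test_that("activity CSV parsing: direct parse, gap flagging, validation", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cage_id,timestamp,activity",
               "C01,2024-01-01T00:00,0.1",
               "C01,2024-01-01T00:01,0.2",
               "C01,2024-01-01T00:02,0.0"), tmp)
  tr <- read_activity_csv(tmp)
  expect_length(tr, 1)
  expect_equal(tr$C01$values, c(0.1, 0.2, 0.0))

  writeLines(c("cage_id,timestamp,activity",
               "C01,2024-01-01T00:00,0.1",
               "C01,2024-01-01T00:02,0.3"), tmp)
  tr <- read_activity_csv(tmp)
  expect_equal(tr$C01$values, c(0.1, NA, 0.3))

  writeLines(c("cage_id,timestamp,activity",
               "C01,2024-01-01T00:00,-0.1"), tmp)
  expect_error(read_activity_csv(tmp), "negative activity")

  writeLines(c("cage,when,act", "C01,2024-01-01T00:00,0.1"), tmp)
  expect_error(read_activity_csv(tmp), "lacks required column")
})

test_that("splitting traces into lights-on-anchored days counts correctly", {
  start <- as.POSIXct("2024-01-01 07:00", tz = "UTC")
  tr <- activity_trace("C01", start, runif(2880))
  d <- split_analysis_days(tr)
  expect_equal(length(d$date), 2)
  expect_true(all(d$valid))

  # 36 h starting 13:00 contains no complete lights-on cycle
  # (07:00 day 2 -> 07:00 day 3 would end past the trace)
  tr2 <- activity_trace("C01", as.POSIXct("2024-01-01 13:00", tz = "UTC"),
                        runif(2160))
  expect_warning(d2 <- split_analysis_days(tr2), "shorter than one")
  expect_equal(sum(d2$valid), 0)
  # extending to 43 h covers exactly one cycle; partials are dropped
  tr2b <- activity_trace("C01", as.POSIXct("2024-01-01 13:00", tz = "UTC"),
                         runif(2580))
  expect_equal(sum(split_analysis_days(tr2b)$valid), 1)

  # non-default schedule shifts the anchor by 60 minutes
  v <- seq_len(2880) - 1
  tr3 <- activity_trace("C01", start, v)
  d3 <- split_analysis_days(tr3, study_calendar("08:00", "20:00"))
  expect_equal(d3$minutes[1, 1], 60)  # first bin at 08:00

  # day/night partition re-concatenates to the original sequence
  d4 <- split_analysis_days(tr3)
  expect_equal(as.vector(t(cbind(d4$minutes[, 1:720], d4$minutes[, 721:1440]))),
               v)

  expect_warning(d5 <- split_analysis_days(
    activity_trace("C01", start, runif(100))), "shorter than one")
  expect_equal(length(d5$date), 0)

  # a missing minute invalidates exactly that day
  vv <- runif(2880); vv[800] <- NA
  d6 <- split_analysis_days(activity_trace("C01", start, vv))
  expect_equal(d6$valid, c(FALSE, TRUE))
  expect_equal(d6$reason[1], "incomplete_day")
})

test_that("exclusion rules: cage-change days and death handling", {
  m <- matrix(runif(7 * 1440), 7)
  days <- days_from_matrix(m)
  cal <- study_calendar(cage_change_dates = list(C01 = as.Date("2024-01-03")))
  out <- apply_exclusions(days, cal)
  expect_equal(sum(out$valid), 6)
  expect_equal(out$reason[out$date == as.Date("2024-01-03")], "cage_change")

  # no calendar events: identity
  out2 <- apply_exclusions(days, study_calendar())
  expect_equal(out2$valid, days$valid)

  meta <- data.frame(cage_id = "C01", genotype = "WT", sex = "M",
                     cohort = "a", entry_date = as.Date("2024-01-01"),
                     n_mice = 2L, endpoint_date = as.Date("2024-01-05"))
  out3 <- apply_exclusions(days, study_calendar(), meta)
  expect_equal(sum(out3$valid), 0)
  expect_true(all(out3$reason == "death_in_cage"))

  out4 <- apply_exclusions(days, study_calendar(), meta,
                           exclude_dead_cage = FALSE)
  expect_equal(out4$date[out4$valid], days$date[1:4])
  expect_equal(unique(out4$reason[!out4$valid]), "after_death")
})

test_that("weekly aggregation averages available days and flags ranges", {
  meta <- data.frame(cage_id = "C01", entry_date = as.Date("2024-01-01"))
  daily <- data.frame(cage_id = "C01",
                      date = as.Date("2024-01-01") + 0:2,
                      metric = "m", value = c(1, 2, 3))
  wk <- weekly_aggregate(daily, meta)
  expect_equal(wk$value, 2)
  expect_equal(wk$week, 7L)
  expect_equal(wk$n_days, 3L)

  # order invariance and equality with the brute-force mean
  daily2 <- daily[sample(3), ]
  expect_equal(weekly_aggregate(daily2, meta)$value, mean(daily$value))

  # identical values are idempotent; all-missing weeks yield NA
  daily3 <- data.frame(cage_id = "C01", date = as.Date("2024-01-01") + 0:6,
                       metric = "m", value = 0.4)
  expect_equal(weekly_aggregate(daily3, meta)$value, 0.4)
  daily4 <- data.frame(cage_id = "C01", date = as.Date("2024-01-01"),
                       metric = "m", value = NA_real_)
  expect_true(is.na(weekly_aggregate(daily4, meta)$value))

  # out-of-window weeks retained but flagged
  daily5 <- data.frame(cage_id = "C01",
                       date = as.Date("2024-01-01") + 7 * 18,
                       metric = "m", value = 1)
  wk5 <- weekly_aggregate(daily5, meta)
  expect_equal(wk5$week, 25L)
  expect_true(wk5$out_of_range)
})

test_that("day-type strata partition valid days with cage-change precedence", {
  # Mon 2024-01-01 .. Sun 2024-01-07
  days <- days_from_matrix(matrix(runif(7 * 1440), 7))
  cal <- study_calendar(cage_change_dates = list(all = as.Date("2024-01-01")),
                        procedure_dates = as.Date("2024-01-02"))
  s <- stratify_by_day_type(days, cal)
  expect_equal(unname(table(s)[c("cage_change", "weekday", "weekend")]),
               c(1L, 4L, 2L), ignore_attr = TRUE)
  expect_false(anyNA(s))  # partition covers all valid days

  # week with no events: 5 weekdays + 2 weekend days
  s2 <- stratify_by_day_type(days, study_calendar())
  expect_equal(sum(s2 == "weekday"), 5)
  expect_equal(sum(s2 == "weekend"), 2)

  # a Saturday cage change is classed cage_change, not weekend
  cal3 <- study_calendar(cage_change_dates = list(all = as.Date("2024-01-06")))
  s3 <- stratify_by_day_type(days, cal3)
  expect_equal(s3[6], "cage_change")

  days$valid[3] <- FALSE
  expect_true(is.na(stratify_by_day_type(days, cal)[3]))
})

test_that("simulated studies round-trip through the file formats", {
  st <- simulate_study(small_cfg(seed = 3, weeks = c(7, 7), cages = 1))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  tr <- read_activity_csv(file.path(dir, "activity.csv"))
  expect_setequal(names(tr), names(st$traces))
  for (id in names(tr))
    expect_equal(tr[[id]]$values, st$traces[[id]]$values, tolerance = 1e-12)
  meta <- read_metadata_csv(file.path(dir, "meta.csv"))
  expect_equal(meta$cage_id, st$meta$cage_id)
  expect_equal(meta$entry_date, st$meta$entry_date)
  cal <- read_calendar_yaml(file.path(dir, "calendar.yaml"))
  expect_equal(cal$lights_on, "07:00")
  expect_equal(cal$cage_change_dates$all, st$calendar$cage_change_dates$all)
})
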