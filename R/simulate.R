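#' Configuration of the home-cage activity simulator
#'
#' The simulator emulates minute-binned activity of pair-housed mice under
#' a 12 h light/dark cycle on a \[0, 1\] activity scale: near-zero light-phase
#' activity with rare short bouts and occasional sub-threshold sensor
#' twitches, a smooth nocturnal drive with peaks after lights-off and
#' before lights-on, and minute-scale bout structure from a two-state
#' (rest/active) Markov chain. "TG" cages add a disease-progression
#' schedule: the diurnal bout rate takes off rapidly at `onset_week`,
#' saturates toward a maximum at `peak_week` and then declines
#' (bell-shaped fragmentation), while the nocturnal amplitude declines
#' linearly from onset (motor impairment).
#' Weekly cage changes inject a strong light-phase activity spike on the
#' scheduled day.
#'
#' @param weeks Age span simulated, in weeks (inclusive).
#' @param cages_per_group Cages per genotype and sex.
#' @param sexes Sexes simulated.
#' @param entry_date Date the cages enter the rack (age = `weeks[1]`).
#' @param twitch_prob,twitch_mean Per-minute probability and mean
#'   (exponential) magnitude of resting sensor twitches (rare, mostly
#'   sub-threshold sensor noise during consolidated rest).
#' @param night_base,peak_height,peak_sd Nocturnal drive: base level plus
#'   two Gaussian peaks (after lights-off, before lights-on) of this height
#'   and width (minutes).
#' @param peak1_min,peak2_min Peak centers, minutes from lights-on.
#' @param drive_noise_frac Multiplicative noise SD on the nocturnal drive.
#' @param rho_day_wt,rho_night Bout initiation rates (bouts/hour) in the
#'   light and dark phase.
#' @param bout_mean_duration Mean bout length in minutes (geometric).
#' @param amp_day,amp_night Per-minute bout amplitude ranges (uniform).
#' @param noise_frac Multiplicative noise SD on bout amplitudes.
#' @param cage_effect_sd SD (log scale) of a per-cage lognormal multiplier
#'   on bout rates, constant over the study; creates the persistent
#'   between-cage differences that correlate weekly outcomes.
#' @param onset_week,peak_week TG effect: first affected week and week of
#'   maximal diurnal fragmentation.
#' @param rho_peak Extra diurnal bout rate (bouts/hour) at the peak week.
#' @param rise_gamma Shape of the onset-to-peak rise (exponent on the
#'   normalized week position; values below 1 give the rapid take-off at
#'   symptomatic onset followed by saturation toward the peak).
#' @param post_peak_decline Fraction of the peak rate lost per week after
#'   the peak.
#' @param night_amp_decline,night_amp_floor Per-week decline of the TG
#'   nocturnal amplitude multiplier from onset, and its floor.
#' @param cage_change_weekday,cage_change_every Weekday (1 = Monday) and
#'   period (weeks) of cage changes.
#' @param cage_change_rho Extra light-phase bout rate (bouts/hour) on cage
#'   change days.
#' @param procedure_weekdays Weekdays with in-room procedures.
#' @param seed Base seed for [simulate_study()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(weeks = c(7L, 24L), cages_per_group = 9L,
                       sexes = c("M", "F"),
                       entry_date = as.Date("2024-01-01"),
                       twitch_prob = 0.005, twitch_mean = 0.003,
                       night_base = 0.05, peak_height = 0.5, peak_sd = 60,
                       peak1_min = 750, peak2_min = 1380,
                       drive_noise_frac = 0.2,
                       rho_day_wt = 0.15, rho_night = 6,
                       bout_mean_duration = 3,
                       amp_day = c(0.05, 0.3), amp_night = c(0.2, 0.8),
                       noise_frac = 0.1, cage_effect_sd = 0.08,
                       onset_week = 16L, peak_week = 20L, rho_peak = 6,
                       rise_gamma = 0.4, post_peak_decline = 0.25,
                       night_amp_decline = 0.08, night_amp_floor = 0.2,
                       cage_change_weekday = 2L, cage_change_every = 1L,
                       cage_change_rho = 30,
                       procedure_weekdays = c(3L, 4L),
                       seed = 1L) {
  stopifnot(length(weeks) == 2, weeks[1] <= weeks[2],
            onset_week <= peak_week, cages_per_group >= 1,
            bout_mean_duration >= 1)
  cfg <- as.list(environment())
  cfg$entry_date <- as.Date(entry_date)
  structure(cfg, class = "sim_config")
}

## TG extra diurnal bout rate at week w (bouts/hour): concave rise from
## onset to peak, then linear decline (bell-shaped fragmentation schedule)
tg_rho_extra <- function(cfg, w) {
  ifelse(w < cfg$onset_week, 0,
         ifelse(w <= cfg$peak_week,
                cfg$rho_peak * ((w - cfg$onset_week + 1) /
                  (cfg$peak_week - cfg$onset_week + 1))^cfg$rise_gamma,
                cfg$rho_peak * pmax(0, 1 - cfg$post_peak_decline *
                                         (w - cfg$peak_week))))
}

## TG nocturnal amplitude multiplier at week w
tg_night_mult <- function(cfg, w) {
  ifelse(w < cfg$onset_week, 1,
         pmax(cfg$night_amp_floor,
              1 - cfg$night_amp_decline * (w - cfg$onset_week)))
}

sim_cage_change_dates <- function(cfg) {
  d0 <- cfg$entry_date + (cfg$cage_change_weekday -
                            as.integer(format(cfg$entry_date, "%u"))) %% 7
  n_weeks <- cfg$weeks[2] - cfg$weeks[1] + 1L
  seq(d0, by = 7L * cfg$cage_change_every,
      length.out = ceiling(n_weeks / cfg$cage_change_every))
}

sim_procedure_dates <- function(cfg) {
  n_weeks <- cfg$weeks[2] - cfg$weeks[1] + 1L
  out <- lapply(cfg$procedure_weekdays, function(wd) {
    d0 <- cfg$entry_date + (wd - as.integer(format(cfg$entry_date, "%u"))) %% 7
    seq(d0, by = 7L, length.out = n_weeks)
  })
  sort(as.Date(unlist(out), origin = "1970-01-01"))
}

#' Simulate one cage's activity trace
#'
#' See [sim_config()] for the generative model. With a fixed seed the
#' output is reproducible bit for bit.
#'
#' @param cfg A [sim_config()].
#' @param genotype `"WT"` or `"TG"`.
#' @param sex `"M"` or `"F"` (label only; the model is sex-symmetric).
#' @param cage_id Cage identifier.
#' @param seed Optional seed set before drawing.
#' @return List with `trace` (an [activity_trace] starting at lights-on on
#'   the entry date) and `truth` (per-week true diurnal bout rates and
#'   nocturnal amplitude multipliers).
#' @export
simulate_cage <- function(cfg, genotype = "WT", sex = "M",
                          cage_id = "C01", seed = NULL) {
  stopifnot(genotype %in% c("WT", "TG"))
  if (!is.null(seed)) set.seed(seed)
  n_weeks <- cfg$weeks[2] - cfg$weeks[1] + 1L
  D <- n_weeks * 7L
  dates <- cfg$entry_date + 0:(D - 1)
  wk <- week_of_age(dates, cfg$entry_date, cfg$weeks[1])
  cc_dates <- sim_cage_change_dates(cfg)

  day_len <- 720L
  is_day <- c(rep(TRUE, day_len), rep(FALSE, 1440L - day_len))
  tmin <- 1:1440
  drive_t <- ifelse(is_day, 0,
                    cfg$night_base +
                      cfg$peak_height * exp(-(tmin - cfg$peak1_min)^2 /
                                              (2 * cfg$peak_sd^2)) +
                      cfg$peak_height * exp(-(tmin - cfg$peak2_min)^2 /
                                              (2 * cfg$peak_sd^2)))

  cage_mult <- exp(rnorm(1, 0, cfg$cage_effect_sd))
  rho_extra <- if (genotype == "TG") tg_rho_extra(cfg, wk) else rep(0, D)
  nmult <- if (genotype == "TG") tg_night_mult(cfg, wk) else rep(1, D)
  rho_day <- cage_mult * (cfg$rho_day_wt + rho_extra) +
    ifelse(dates %in% cc_dates, cfg$cage_change_rho, 0)
  rho_night_c <- cage_mult * cfg$rho_night

  ## per-minute transition probabilities of the rest/active chain
  p01 <- outer(rho_day / 60, as.numeric(is_day)) +
    outer(rep(rho_night_c / 60, D), as.numeric(!is_day))
  p01 <- pmin(p01, 1)
  p10 <- 1 / cfg$bout_mean_duration

  S <- matrix(0L, D, 1440L)
  S[, 1] <- as.integer(runif(D) < p01[, 1] / (p01[, 1] + p10))
  for (t in 2:1440) {
    u <- runif(D)
    S[, t] <- ifelse(S[, t - 1] == 1L, as.integer(u >= p10),
                     as.integer(u < p01[, t]))
  }

  on_change_day <- matrix(dates %in% cc_dates, D, 1440L)
  day_mask <- matrix(is_day, D, 1440L, byrow = TRUE)
  lo <- ifelse(day_mask & !on_change_day, cfg$amp_day[1], cfg$amp_night[1])
  hi <- ifelse(day_mask & !on_change_day, cfg$amp_day[2], cfg$amp_night[2])
  amp <- matrix(runif(D * 1440L), D, 1440L) * (hi - lo) + lo
  amp <- amp * pmax(0, 1 + matrix(rnorm(D * 1440L, 0, cfg$noise_frac),
                                  D, 1440L))
  amp[!day_mask] <- amp[!day_mask] * rep(nmult, sum(!is_day))

  drive <- outer(nmult, drive_t)
  drive <- drive * pmax(0, 1 + matrix(rnorm(D * 1440L, 0,
                                            cfg$drive_noise_frac), D, 1440L))

  twitch <- matrix(rbinom(D * 1440L, 1L, cfg$twitch_prob) *
                     rexp(D * 1440L, 1 / cfg$twitch_mean), D, 1440L)

  x <- drive + S * amp + (1L - S) * twitch
  x <- pmin(pmax(x, 0), 1)

  start <- as.POSIXct(paste(cfg$entry_date, "07:00:00"), tz = "UTC")
  truth <- data.frame(cage_id = cage_id, week = wk[seq(1, D, by = 7)],
                      cage_mult = cage_mult,
                      rho_day = cage_mult *
                        (cfg$rho_day_wt + rho_extra[seq(1, D, by = 7)]),
                      night_amp_mult = nmult[seq(1, D, by = 7)],
                      genotype = genotype,
                      onset_week = if (genotype == "TG") cfg$onset_week else NA,
                      peak_week = if (genotype == "TG") cfg$peak_week else NA,
                      stringsAsFactors = FALSE)
  list(trace = activity_trace(cage_id, start, as.vector(t(x))), truth = truth)
}

#' Simulate a complete study
#'
#' Generates every cage of the configured design (both genotypes and
#' sexes), the matching metadata table, study calendar and ground truth.
#' Per-cage seeds are derived from `cfg$seed` so the study is reproducible.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_study`: `traces` (named list of
#'   [activity_trace]), `meta` (`cage_metadata`), `calendar`
#'   ([study_calendar]), `truth` (`data.frame`).
#' @export
simulate_study <- function(cfg = sim_config()) {
  design <- expand.grid(idx = seq_len(cfg$cages_per_group),
                        genotype = c("WT", "TG"), sex = cfg$sexes,
                        stringsAsFactors = FALSE)
  design$cage_id <- sprintf("%s_%s_%02d", design$sex, design$genotype,
                            design$idx)
  traces <- vector("list", nrow(design))
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sim <- simulate_cage(cfg, design$genotype[i], design$sex[i],
                         design$cage_id[i],
                         seed = (cfg$seed * 1000L + i) %% .Machine$integer.max)
    traces[[i]] <- sim$trace
    truth[[i]] <- sim$truth
  }
  names(traces) <- design$cage_id
  meta <- data.frame(cage_id = design$cage_id, genotype = design$genotype,
                     sex = design$sex, cohort = "sim",
                     entry_date = cfg$entry_date, n_mice = 2L,
                     endpoint_date = as.Date(NA), stringsAsFactors = FALSE)
  class(meta) <- c("cage_metadata", "data.frame")
  cal <- study_calendar(cage_change_dates =
                          list(all = sim_cage_change_dates(cfg)),
                        procedure_dates = sim_procedure_dates(cfg))
  structure(list(traces = traces, meta = meta, calendar = cal,
                 truth = do.call(rbind, truth), config = cfg),
            class = "sim_study")
}

#' Write a simulated study to disk in the package's file formats
#'
#' Emits `activity.csv` (long format: cage_id, timestamp, activity),
#' `meta.csv`, `calendar.yaml` and `truth.json`, all readable by the
#' corresponding `read_*` functions.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  act <- do.call(rbind, lapply(study$traces, function(tr) {
    n <- length(tr$values)
    keep <- !is.na(tr$values)
    data.frame(cage_id = tr$cage_id,
               timestamp = format(tr$start + (seq_len(n) - 1) * 60,
                                  "%Y-%m-%dT%H:%M", tz = "UTC"),
               activity = tr$values, stringsAsFactors = FALSE)[keep, ]
  }))
  paths <- file.path(dir, c("activity.csv", "meta.csv", "calendar.yaml",
                            "truth.json"))
  write.csv(act, paths[1], row.names = FALSE, quote = FALSE)
  m <- study$meta
  m$entry_date <- format(m$entry_date)
  m$endpoint_date <- ifelse(is.na(m$endpoint_date), "",
                            format(m$endpoint_date))
  write.csv(m, paths[2], row.names = FALSE, quote = FALSE)
  cal <- study$calendar
  yaml::write_yaml(list(lights_on = cal$lights_on,
                        lights_off = cal$lights_off,
                        cage_change = lapply(cal$cage_change_dates, format),
                        procedures = format(cal$procedure_dates)), paths[3])
  jsonlite::write_json(study$truth, paths[4], dataframe = "rows")
  invisible(paths)
}
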