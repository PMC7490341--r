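# Small simulated studies shared across test files.

small_cfg <- function(seed = 1, weeks = c(7, 9), cages = 2, ...) {
  sim_config(weeks = weeks, cages_per_group = cages, sexes = "M",
             seed = seed, ...)
}

# A single complete analysis day with a given structure, as a plain vector.
toy_day <- function(seed = 1, night_level = 0.4, day_level = 0, noise = 0.05) {
  set.seed(seed)
  day <- pmax(0, rnorm(720, day_level, noise * (day_level > 0)))
  night <- pmax(0, rnorm(720, night_level, noise))
  c(day, night)
}

# analysis_days object built directly from a matrix of day vectors.
days_from_matrix <- function(m, cage_id = "C01",
                             dates = as.Date("2024-01-01") + seq_len(nrow(m)) - 1) {
  structure(list(cage_id = cage_id, date = dates, minutes = m,
                 day_len = 720L, valid = rep(TRUE, nrow(m)),
                 reason = rep("", nrow(m))),
            class = "analysis_days")
}
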