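test_that("thresholding uses the strict-below convention and is idempotent", {
  expect_equal(threshold_activity(c(0.004, 0.005, 0.006), 0.005),
               c(0, 0.005, 0.006))
  expect_equal(threshold_activity(rep(0, 10), 0.005), rep(0, 10))
  x <- runif(100)
  expect_equal(threshold_activity(x, 0), x)
  y <- threshold_activity(x, 0.3)
  expect_equal(threshold_activity(y, 0.3), y)
  expect_error(threshold_activity(c(-1, 0)), "nonnegative")
})

test_that("band-pass rejects DC and matches its analytic response", {
  p <- rdi_params()
  out <- bandpass_filter(rep(0.5, 720), p)
  expect_lt(max(abs(out)), 1e-9 * 0.5)

  # steady-state amplitude of in- and out-of-band sinusoids vs |H|^2
  sos <- butter_bandpass_sos(p$filter_order, p$f_low, p$f_high)
  n <- 20000; t <- seq_len(n)
  f_mid <- sqrt(p$f_low * p$f_high)      # geometric band center (x Nyquist)
  s <- sin(pi * f_mid * t)
  amp <- max(abs(sos_filtfilt(sos, s)[(n / 2 - 2000):(n / 2 + 2000)]))
  expect_equal(amp, sos_freq_response(sos, f_mid)^2, tolerance = 0.05)
  expect_gt(amp, 0.95)

  f_stop <- 10 * p$f_high
  s2 <- sin(pi * f_stop * t)
  amp2 <- max(abs(sos_filtfilt(sos, s2)[(n / 2 - 2000):(n / 2 + 2000)]))
  expect_lt(amp2, 0.10)

  expect_error(bandpass_filter(runif(10), p), "segment_too_short")
})

test_that("zero-phase SOS filtering reproduces reference filtfilt output", {
  # frozen outputs of an independent SOS forward-backward implementation
  # (scipy.signal sosfiltfilt, padlen 27) on a deterministic 720-min input
  sos <- butter_bandpass_sos(4, 1 / 2000, 1 / 300)
  t <- 0:719
  x <- abs(sin(2 * pi * t / 144)) * 0.3 + 0.02 * sin(t) + 0.05
  y <- sos_filtfilt(sos, x, padlen = 27)
  expect_equal(y[c(1, 101, 360, 501, 720)],
               c(-0.006881718852, 0.094944596411, 0.078271440462,
                 0.016738485829, 0.000000585518),
               tolerance = 1e-6)
  expect_equal(sum(y^2), 4.2338790375, tolerance = 1e-7)
})

test_that("centered moving average shrinks at edges and matches brute force", {
  expect_equal(moving_average(rep(3, 100), 60), rep(3, 100))
  expect_equal(moving_average(1:5, 1), 1:5)
  expect_error(moving_average(1:5, 6), "longer than series")

  x <- numeric(300); x[150] <- 60
  sm <- moving_average(x, 60)
  expect_equal(max(sm), 1)
  expect_equal(sum(sm > 0.99), 60)

  set.seed(42)
  z <- runif(200)
  w <- 30
  brute <- vapply(seq_along(z), function(t) {
    idx <- max(1, t - w %/% 2):min(length(z), t + w - w %/% 2 - 1)
    mean(z[idx])
  }, numeric(1))
  expect_equal(moving_average(z, w), brute)
})

test_that("peak normalization yields max 1 and handles degenerate input", {
  expect_equal(normalize_to_peak(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_warning(out <- normalize_to_peak(rep(0, 5)), "all-zero")
  expect_equal(out, rep(0, 5))
  x <- runif(100)
  nx <- normalize_to_peak(x)
  expect_equal(max(nx), 1)
  expect_equal(normalize_to_peak(nx), nx)
})

test_that("least active hour minimizes over all windows with earliest ties", {
  d <- runif(1440, 0.5, 1); d[101:160] <- 0
  lah <- find_least_active_hour(d)
  expect_equal(lah$start_minute, 100L)
  expect_equal(lah$mean_activity, 0)
  expect_equal(lah$segment, d[101:160])

  expect_equal(find_least_active_hour(rep(0.3, 1440))$start_minute, 0L)
  d2 <- runif(1440, 0.5, 1); d2[201:260] <- 0.1; d2[901:960] <- 0.1
  expect_equal(find_least_active_hour(d2)$start_minute, 200L)

  # brute-force scan of all 1381 windows
  set.seed(7)
  for (i in 1:5) {
    x <- runif(1440)
    lah <- find_least_active_hour(x)
    means <- vapply(1:1381, function(s) mean(x[s:(s + 59)]), numeric(1))
    expect_equal(lah$start_minute, which.min(means) - 1L)
    expect_lte(lah$mean_activity, min(means) + 1e-12)
  }

  expect_error(find_least_active_hour(c(NA, runif(1439))), "incomplete")
})
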