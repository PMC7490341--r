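test_that("pooled t-test uses pooled-variance degrees of freedom", {
  set.seed(1)
  expect_equal(pooled_t_test(rnorm(8), rnorm(9))$df, 15)
  expect_equal(pooled_t_test(rnorm(11), rnorm(10))$df, 19)

  x <- c(1, 2, 3)
  res <- pooled_t_test(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # hand-computed closed form on a small printed example
  a <- c(1.1, 2.3, 0.8); b <- c(2.0, 2.9, 3.4)
  or <- brute_pooled_t(a, b)
  got <- pooled_t_test(a, b)
  expect_equal(got$t, or$t, tolerance = 1e-12)
  expect_equal(got$p, or$p, tolerance = 1e-12)
  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")
})

test_that("r-bar estimation averages pairwise week correlations", {
  m <- matrix(rep(rnorm(10), 4), 10, 4)  # identical columns
  expect_equal(estimate_rbar(m), 1)

  # independent columns: near 0 after clipping
  set.seed(2)
  big <- matrix(rnorm(1000 * 5), 1000, 5)
  expect_lt(estimate_rbar(big), 0.05)

  # common-factor construction with known correlation 0.5
  set.seed(3)
  f <- rnorm(2000)
  m2 <- sapply(1:4, function(i) f + rnorm(2000))
  cm <- cor(m2)
  expect_equal(estimate_rbar(m2), mean(cm[upper.tri(cm)]), tolerance = 1e-12)
  expect_equal(estimate_rbar(m2), 0.5, tolerance = 0.05)

  m3 <- cbind(rnorm(10), rep(1, 10), rnorm(10))
  expect_warning(estimate_rbar(m3), "zero-variance")
  expect_error(estimate_rbar(matrix(rnorm(4), 2, 2)), "at least 3 cages")
})

test_that("D/AP adjustment has the right limits and monotonicity", {
  a <- 0.05
  expect_equal(dap_adjust(a, 14, 1), a)
  expect_equal(dap_adjust(a, 2, 0), 1 - 0.95^(1 / 2))
  expect_equal(dap_adjust(a, 1, 0.7), a)
  rb <- seq(0, 1, by = 0.05)
  vals <- vapply(rb, function(r) dap_adjust(a, 10, r), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(dap_adjust(a, 10, 0), a / 10)  # Sidak is wider than Bonferroni
})

test_that("correction schemes nest: Bonferroni within D/AP within raw", {
  set.seed(4)
  meta <- data.frame(cage_id = sprintf("C%02d", 1:10),
                     genotype = rep(c("WT", "TG"), each = 5),
                     entry_date = as.Date("2024-01-01"))
  for (i in 1:20) {
    vals <- expand.grid(cage_id = meta$cage_id, week = 7:14)
    vals$metric <- "m"
    vals$value <- rnorm(nrow(vals)) +
      2 * (vals$week > 10) * (meta$genotype[match(vals$cage_id,
                                                  meta$cage_id)] == "TG")
    ph <- posthoc_weeks(vals, meta, max_week = 20)
    expect_true(all(!ph$sig_bonferroni | ph$sig_dap))
    expect_true(all(!ph$sig_dap | ph$sig_none))
  }
})

test_that("single tested week reduces every scheme to the raw test", {
  meta <- data.frame(cage_id = sprintf("C%02d", 1:8),
                     genotype = rep(c("WT", "TG"), each = 4),
                     entry_date = as.Date("2024-01-01"))
  vals <- data.frame(cage_id = meta$cage_id, week = 10L, metric = "m",
                     value = c(1, 2, 1.5, 1.2, 4, 5, 4.4, 4.8))
  ph <- posthoc_weeks(vals, meta)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$sig_none, ph$sig_bonferroni)
  expect_equal(ph$sig_none, ph$sig_dap)
  expect_equal(attr(ph, "k"), 1L)
})

test_that("onset is the earliest D/AP-significant week", {
  ph <- data.frame(week = 14:17, sig_dap = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(detect_onset(ph), 16L)
  ph$sig_dap <- FALSE
  expect_true(is.na(detect_onset(ph)))
})

test_that("weeks beyond the testing horizon and incomplete weeks drop", {
  meta <- data.frame(cage_id = c("A", "B", "C", "D"),
                     genotype = c("WT", "WT", "TG", "TG"),
                     entry_date = as.Date("2024-01-01"))
  vals <- expand.grid(cage_id = meta$cage_id, week = 18:22)
  vals$metric <- "m"
  set.seed(8)
  vals$value <- rnorm(nrow(vals))
  vals$value[vals$cage_id == "A" & vals$week == 19] <- NA  # incomplete week
  ph <- posthoc_weeks(vals, meta, max_week = 20)
  expect_equal(ph$week, c(18, 20))
  expect_equal(attr(ph, "dropped_weeks"), 19)
})
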