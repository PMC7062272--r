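test_that("criterion 1 is inclusive at the cutoff and missing-aware", {
  expect_true(crit1_met(30, 23, 7))   # a drop of exactly 7 counts
  expect_false(crit1_met(30, 24, 7))  # 6 < 7
  expect_identical(crit1_met(NA, 24, 7), NA)
  expect_identical(crit1_met(30, NA, 7), NA)
  # losses invert the direction
  expect_true(crit1_met(23, 30, 7, direction = "loss"))
  expect_false(crit1_met(30, 23, 7, direction = "loss"))
  expect_error(crit1_met(30, 23, 0), "positive")
  expect_error(crit1_met(30, 23, -2), "positive")
})

test_that("criterion 2 compares the drop against a fraction of the pre-gain score", {
  expect_true(crit2_met(40, 30, 0.25))   # 10 is exactly 25% of 40
  expect_false(crit2_met(40, 31, 0.25))  # 9 < 10
  expect_identical(crit2_met(NA, 30), NA)
  expect_identical(crit2_met(40, NA), NA)
  # a percentage drop from a non-positive score is undefined -> not met
  expect_warning(res <- crit2_met(0, 0, 0.25), "non-positive")
  expect_false(res)
  expect_warning(res <- crit2_met(-3, -10, 0.25, direction = "gain"),
                 "non-positive")
  expect_false(res)
  expect_error(crit2_met(40, 30, 1.2), "0, 1")
})

test_that("critical values reproduce the adjusted t quantiles and grow as data go missing", {
  expect_equal(sg_critical_value(3, 3), 2.776, tolerance = 1e-3)
  expect_equal(sg_critical_value(3, 2), 3.182, tolerance = 1e-3)
  expect_equal(sg_critical_value(2, 2), 4.303, tolerance = 1e-3)
  # monotone in decreasing df for any alpha
  for (alpha in c(0.01, 0.05, 0.1, 0.2, 0.4)) {
    expect_lt(sg_critical_value(3, 3, alpha), sg_critical_value(3, 2, alpha))
    expect_lt(sg_critical_value(3, 2, alpha), sg_critical_value(2, 2, alpha))
  }
  expect_error(sg_critical_value(1, 3), "at least 2")
  expect_error(sg_critical_value(3, 3, alpha = 1), "between 0 and 1")
})

test_that("criterion 3 matches hand-computed window statistics", {
  # full windows: M_pre 29, M_post 17, pooled SD 1, 12 > 2.776
  res <- crit3_met(c(30, 29, 28), c(18, 17, 16))
  expect_true(as.logical(res))
  expect_equal(attr(res, "critical_value_used"), stats::qt(0.975, 4))

  # strict inequality: identical flat windows fail (0 > 0 is false)
  expect_false(as.logical(crit3_met(c(20, 20, 20), c(20, 20, 20))))

  # missing-data pattern: 2 + 2 points, critical value 4.303,
  # 11.5 > 4.303 * sqrt(1.25)
  res <- crit3_met(c(30, NA, 28), c(18, 17, NA))
  expect_true(as.logical(res))
  expect_equal(attr(res, "critical_value_used"), stats::qt(0.975, 2))

  # fewer than two points on one side -> not testable
  expect_identical(as.logical(crit3_met(c(NA, NA, 28), c(18, 17, 16))), NA)
  expect_identical(as.logical(crit3_met(c(30, 29, 28), c(18, NA, NA))), NA)

  # degenerate zero pooled SD reduces to comparing the means
  expect_true(as.logical(crit3_met(c(20, 20, 20), c(10, 10, 10))))

  # fixed critical value applied when adjustment is off
  res <- crit3_met(c(30, NA, 28), c(18, 17, NA), sg_crit3_adjust = FALSE,
                   sg_crit3_critical_value = 2.776)
  expect_equal(attr(res, "critical_value_used"), 2.776)
})

test_that("criterion 3 agrees with an independent pooled-variance t test", {
  # the comparison M_pre - M_post > c * pooled_sd is equivalent to the
  # two-sample pooled t statistic exceeding c / sqrt(1/n_pre + 1/n_post)
  withr::with_seed(42, {
    for (rep in seq_len(500)) {
      n1 <- sample(2:3, 1)
      n2 <- sample(2:3, 1)
      pre <- round(stats::rnorm(n1, 25, 8), 1)
      post <- round(stats::rnorm(n2, 18, 8), 1)
      if (stats::sd(pre) == 0 && stats::sd(post) == 0) next
      got <- as.logical(crit3_met(pre, post))
      t_stat <- stats::t.test(pre, post, var.equal = TRUE)$statistic
      c_val <- stats::qt(0.975, n1 + n2 - 2)
      want <- unname(t_stat > c_val / sqrt(1 / n1 + 1 / n2))
      expect_identical(got, want)
    }
  })
})

test_that("interval evaluability requires the four-point minimum patterns", {
  # the four canonical minimum patterns
  expect_true(pattern_evaluable(c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)))
  expect_true(pattern_evaluable(c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)))
  expect_true(pattern_evaluable(c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)))
  expect_true(pattern_evaluable(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)))
  # mandatory pre/post-gain points
  expect_false(pattern_evaluable(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)))
  expect_false(pattern_evaluable(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)))
  # exhaustive: evaluable iff x_n & x_n1 present and >= 2 present per side,
  # and never with fewer than 4 present points overall
  for (code in 0:63) {
    w <- as.logical(bitwAnd(bitwShiftR(code, 0:5), 1L))
    want <- w[3] && w[4] && sum(w[1:3]) >= 2 && sum(w[4:6]) >= 2
    expect_identical(pattern_evaluable(w), want)
    if (sum(w) < 4) expect_false(pattern_evaluable(w))
  }
})

test_that("check_interval composes the three criteria over one interval", {
  x <- gain_series(n = 5)
  res <- check_interval(x, 5, sg_crit1_cutoff = 7)
  expect_identical(res$sg, 1L)
  expect_true(res$sg_crit1 && res$sg_crit2 && res$sg_crit3)
  expect_identical(res$n_pre, 3L)
  expect_identical(res$n_post, 3L)
  expect_equal(res$critical_value_used, stats::qt(0.975, 4))

  # a fully missing series can never be classified
  empty <- rep(NA_real_, 12)
  for (n in 1:11) {
    expect_identical(check_interval(empty, n, sg_crit1_cutoff = 7)$sg,
                     NA_integer_)
  }

  # a constant series is classifiable everywhere inside the span, never a gain
  flat <- rep(20, 12)
  for (n in 2:10) {
    expect_identical(check_interval(flat, n, sg_crit1_cutoff = 7)$sg, 0L)
  }

  # boundary pre-gain sessions lack a full window on one side
  expect_identical(check_interval(flat, 1, sg_crit1_cutoff = 7)$sg,
                   NA_integer_)
  expect_identical(check_interval(flat, 11, sg_crit1_cutoff = 7)$sg,
                   NA_integer_)
  expect_error(check_interval(flat, 12, sg_crit1_cutoff = 7), "between 1 and 11")
  expect_error(check_interval(flat, 0, sg_crit1_cutoff = 7), "between 1 and 11")
})

test_that("an unclassifiable pattern yields NA even when some criteria computed", {
  # pre/post-gain points present, small drop (criterion 1 clearly fails),
  # but only one post-window point: the combined verdict stays NA
  x <- c(NA, 25, 24, 23, NA, NA, 10, 10, 10, 10, 10, 10)
  res <- check_interval(x, 3, sg_crit1_cutoff = 7)
  expect_false(res$sg_crit1)
  expect_identical(res$sg_crit3, NA)
  expect_identical(res$sg, NA_integer_)

  # ... while with a complete pattern a definite failure yields 0 even if
  # criterion 3 alone passes
  y <- c(14, 13, 12, 11, 10, 9, 9, 9, 9, 9, 9, 9)
  res <- check_interval(y, 5, sg_crit1_cutoff = 7)
  expect_false(res$sg_crit1)
  expect_true(res$sg_crit3)
  expect_identical(res$sg, 0L)
})

test_that("check_interval is pure and loss verdicts mirror gains on negated data", {
  x <- gain_series(n = 6)
  expect_identical(check_interval(x, 6, sg_crit1_cutoff = 7),
                   check_interval(x, 6, sg_crit1_cutoff = 7))

  withr::with_seed(7, {
    for (rep in seq_len(50)) {
      x <- round(stats::rnorm(12, 25, 8))
      x[sample(12, sample(0:3, 1))] <- NA
      n <- sample(2:10, 1)
      gain <- check_interval(x, n, sg_crit1_cutoff = 7, sg_crit2 = FALSE)
      loss <- check_interval(-x, n, sg_crit1_cutoff = 7, sg_crit2 = FALSE,
                             direction = "loss")
      expect_identical(gain$sg_crit1, loss$sg_crit1)
      expect_identical(gain$sg_crit3, loss$sg_crit3)
      expect_identical(gain$sg, loss$sg)
    }
  })
})
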