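test_that("the reversal threshold is the midpoint of the gain", {
  expect_equal(reversal_value(40, 30), 35)
  expect_equal(reversal_value(30, 30), 30)
  expect_equal(reversal_value(28, 18), 23)
  expect_error(reversal_value(NA, 30), "present")
})

test_that("a reversal needs a later score at or beyond the threshold", {
  expect_true(reversal_occurred(c(31, 36, 30), 35))
  expect_true(reversal_occurred(c(31, 35, 30), 35))  # "35 or more" is inclusive
  expect_false(reversal_occurred(c(34, 30), 35))
  expect_false(reversal_occurred(numeric(0), 35))    # final-interval gain
  expect_false(reversal_occurred(c(NA, NA), 35))
  # losses mirror: a later score at or below the midpoint
  expect_true(reversal_occurred(c(36, 34), 35, direction = "loss"))
  expect_false(reversal_occurred(c(37, 36), 35, direction = "loss"))
})

test_that("bysg rows carry the full per-gain variable set", {
  # around-gain values 30,29,28 | 18,17,16 with treatment course 32 -> 12
  x <- c(32, 31, 30, 29, 28, 18, 17, 16, 15, 14, 13, 12)
  data <- wide_data(x, rep(20, 12))
  bysg <- create_bysg(data, "id", session_vars(12), "bdi_s1", "bdi_s12",
                      sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  expect_identical(nrow(bysg), 1L)
  rec <- bysg[1, ]
  expect_identical(rec$id_sg, "1_sg5")
  expect_identical(rec$sg_session_n, 5L)
  expect_identical(rec$sg_freq_byperson, 1L)
  expect_equal(unlist(rec[paste0("sg_bdi_", c("2n", "1n", "n",
                                              "n1", "n2", "n3"))]),
               c(30, 29, 28, 18, 17, 16), ignore_attr = TRUE)
  expect_equal(rec$sg_magnitude, 10)
  expect_equal(rec$sg_bdi_tx_change, 20)
  expect_equal(rec$sg_change_proportion, 0.5)
  expect_equal(rec$sg_reversal_value, 23)
  expect_identical(rec$sg_reversal, 0L)
  # raw session scores travel with the record
  expect_equal(rec$bdi_s1, 32)
})

test_that("gain records match the flag table and recompute from raw data", {
  demo <- sg_demo_data()
  vars <- session_vars(12)
  flags <- identify_sg(demo, "id", vars, sg_crit1_cutoff = 7)
  bysg <- create_bysg(demo, "id", vars, "bdi_s1", "bdi_s12",
                      sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  hits <- flagged_positions(flags)
  expect_identical(nrow(bysg), nrow(hits))
  expect_identical(bysg$id, hits$id)
  expect_identical(bysg$sg_session_n, hits$session_n)
  # per-person frequencies sum to the record count
  expect_identical(sum(tapply(bysg$sg_freq_byperson, bysg$id, unique)),
                   nrow(bysg))
  # every stored field recomputes from the raw series
  for (k in seq_len(nrow(bysg))) {
    x <- as.numeric(demo[demo$id == bysg$id[k], vars])
    n <- bysg$sg_session_n[k]
    expect_equal(bysg$sg_magnitude[k], x[n] - x[n + 1])
    expect_gte(bysg$sg_magnitude[k], 7)
    expect_equal(bysg$sg_reversal_value[k], (x[n] + x[n + 1]) / 2)
    later <- if (n + 2 <= 12) x[(n + 2):12] else numeric(0)
    expect_identical(bysg$sg_reversal[k] == 1L,
                     reversal_occurred(later, bysg$sg_reversal_value[k]))
  }
})

test_that("a gainless dataset yields an empty bysg with the full schema", {
  data <- wide_data(rep(20, 12), rep(25, 12))
  bysg <- create_bysg(data, "id", session_vars(12), "bdi_s1", "bdi_s12",
                      sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  expect_identical(nrow(bysg), 0L)
  expect_true(all(c("id_sg", "id", "sg_crit123", "sg_session_n",
                    "sg_freq_byperson", "sg_bdi_n", "sg_magnitude",
                    "sg_bdi_tx_change", "sg_change_proportion",
                    "sg_reversal_value", "sg_reversal") %in% names(bysg)))
})

test_that("byperson covers every subject and honours the multi-gain selector", {
  two_gains <- c(50, 49, 48, 36, 35, 34, 33, 20, 19, 18, 17, 16)
  data <- wide_data(two_gains, gain_series(n = 5), rep(20, 12))
  args <- list(data, "id", session_vars(12), "bdi_s1", "bdi_s12",
               sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  byp <- do.call(create_byperson, args)
  expect_identical(nrow(byp), 3L)
  expect_identical(byp$sg_crit123, c(1L, 1L, 0L))
  expect_identical(byp$sg_freq_byperson, c(2L, 1L, 0L))
  expect_true(is.na(byp$sg_session_n[3]))
  expect_true(is.na(byp$id_sg[3]))
  # subject 1 gains at 3 -> 4 (magnitude 12) and 7 -> 8 (magnitude 13)
  expect_identical(byp$sg_session_n[1], 3L)  # default: first
  sel <- function(mode) {
    do.call(create_byperson, c(args, list(multiple_sg_select = mode)))
  }
  expect_identical(sel("last")$sg_session_n[1], 7L)
  expect_identical(sel("smallest")$sg_session_n[1], 3L)
  expect_identical(sel("largest")$sg_session_n[1], 7L)
})

test_that("byperson gainers under selector 'first' derive from bysg", {
  demo <- sg_demo_data()
  vars <- session_vars(12)
  bysg <- create_bysg(demo, "id", vars, "bdi_s1", "bdi_s12",
                      sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  byp <- create_byperson(demo, "id", vars, "bdi_s1", "bdi_s12",
                         sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  first <- do.call(rbind, lapply(split(bysg, bysg$id), function(d) {
    d[which.min(d$sg_session_n), c("id", "sg_session_n", "sg_magnitude")]
  }))
  gainers <- byp[byp$sg_crit123 == 1L, c("id", "sg_session_n", "sg_magnitude")]
  expect_equal(gainers[order(gainers$id), ],
               first[order(first$id), ], ignore_attr = TRUE)
})

test_that("an unhelpful total treatment change gives a missing proportion", {
  # net deterioration over treatment despite a sudden gain
  x <- c(30, 29, 28, 18, 17, 16, 20, 28, 33, 36, 38, 40)
  data <- wide_data(x)
  expect_warning(
    bysg <- create_bysg(data, "id", session_vars(12), "bdi_s1", "bdi_s12",
                        sg_crit1_cutoff = 7, sg_measure_name = "bdi"),
    "proportion")
  expect_true(is.na(bysg$sg_change_proportion[1]))
  expect_equal(bysg$sg_bdi_tx_change[1], -10)
})

test_that("secondary values are pulled from the sessions around each gain", {
  x <- gain_series(n = 5)
  data <- wide_data(x)
  for (t in 1:12) data[[paste0("rq_s", t)]] <- 100 + t  # value encodes session
  bysg <- create_bysg(data, "id", session_vars(12), "bdi_s1", "bdi_s12",
                      sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  bysg <- dplyr::left_join(bysg, data[, c("id", session_vars(12, "rq_s"))],
                           by = "id")
  attr(bysg, "sg_n_sessions") <- 12L
  out <- extract_values(bysg, "id_sg", session_vars(12, "rq_s"), "rq")
  expect_equal(unlist(out[1, paste0("sg_rq_", c("2n", "1n", "n",
                                                "n1", "n2", "n3"))]),
               100 + c(3, 4, 5, 6, 7, 8), ignore_attr = TRUE)

  # a gain at the first evaluable interval has no N-2 session
  x2 <- c(40, 39, 27, 26, 25, 25, 24, 24, 23, 23, 22, 22)
  data2 <- wide_data(x2)
  for (t in 1:12) data2[[paste0("rq_s", t)]] <- 100 + t
  bysg2 <- create_bysg(data2, "id", session_vars(12), "bdi_s1", "bdi_s12",
                       sg_crit1_cutoff = 7, sg_measure_name = "bdi")
  expect_identical(bysg2$sg_session_n, 2L)
  bysg2 <- dplyr::left_join(bysg2, data2[, c("id", session_vars(12, "rq_s"))],
                            by = "id")
  attr(bysg2, "sg_n_sessions") <- 12L
  out2 <- extract_values(bysg2, "id_sg", session_vars(12, "rq_s"), "rq")
  expect_true(is.na(out2$sg_rq_2n[1]))
  expect_equal(out2$sg_rq_1n[1], 101)

  # the secondary series must align with the primary timepoints
  expect_error(
    extract_values(bysg, "id_sg", session_vars(11, "rq_s"), "rq"),
    "same.*timepoints")
})
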