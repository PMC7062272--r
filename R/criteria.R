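#' Critical value for the symptom-fluctuation criterion
#'
#' Returns the two-tailed Student-t quantile used in the third sudden-gains
#' criterion, with degrees of freedom determined by how many of the three
#' pre-gain and three post-gain measurements are actually available.
#' With full windows (3 + 3) the value is 2.776; with one point missing on
#' one side (3 + 2) it is 3.182; with one point missing on both sides
#' (2 + 2) it is 4.303 (at `alpha = 0.05`).
#'
#' @param n_pre Number of available pre-gain measurements (2 or 3).
#' @param n_post Number of available post-gain measurements (2 or 3).
#' @param alpha Two-tailed alpha level; the quantile returned is
#'   `qt(1 - alpha / 2, df = n_pre + n_post - 2)`. Default 0.05.
#'
#' @return A single positive number.
#' @export
#' @examples
#' sg_critical_value(3, 3) # 2.776
#' sg_critical_value(3, 2) # 3.182
#' sg_critical_value(2, 2) # 4.303
sg_critical_value <- function(n_pre, n_post, alpha = 0.05) {
  if (!is.numeric(n_pre) || length(n_pre) != 1L || is.na(n_pre) ||
      !is.numeric(n_post) || length(n_post) != 1L || is.na(n_post) ||
      n_pre != round(n_pre) || n_post != round(n_post)) {
    stop("`n_pre` and `n_post` must be single whole numbers.", call. = FALSE)
  }
  if (n_pre < 2 || n_post < 2) {
    stop("`n_pre` and `n_post` must each be at least 2 ",
         "(fewer points leave the window standard deviation undefined).",
         call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number strictly between 0 and 1.",
         call. = FALSE)
  }
  df <- n_pre + n_post - 2
  stats::qt(1 - alpha / 2, df = df)
}

#' First criterion: absolute magnitude of change
#'
#' Tests whether the change from the pre-gain score `x_n` to the post-gain
#' score `x_n1` is at least `sg_crit1_cutoff` points in the direction of
#' interest (a decrease for gains, an increase for losses). The comparison
#' is inclusive ("at least").
#'
#' @param x_n Pre-gain score(s); `NA` for missing.
#' @param x_n1 Post-gain score(s); `NA` for missing.
#' @param sg_crit1_cutoff Positive cutoff in score units (e.g. 7 BDI points).
#' @param direction `"gain"` (improvement = decrease) or `"loss"`.
#'
#' @return Logical vector: `TRUE` (met), `FALSE` (not met), `NA`
#'   (cannot be tested because a score is missing).
#' @export
#' @examples
#' crit1_met(30, 23, 7) # TRUE: drop of exactly 7
#' crit1_met(30, 24, 7) # FALSE: drop of 6
crit1_met <- function(x_n, x_n1, sg_crit1_cutoff, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (!is.numeric(sg_crit1_cutoff) || length(sg_crit1_cutoff) != 1L ||
      is.na(sg_crit1_cutoff) || sg_crit1_cutoff <= 0) {
    stop("`sg_crit1_cutoff` must be a single positive number.", call. = FALSE)
  }
  change <- if (direction == "gain") x_n - x_n1 else x_n1 - x_n
  change >= sg_crit1_cutoff
}

#' Second criterion: change relative to the previous score
#'
#' Tests whether the change from `x_n` to `x_n1` amounts to at least
#' `sg_crit2_pct` (default 25%) of the pre-change score `x_n`. A percentage
#' change is undefined from a non-positive score, so `x_n <= 0` yields
#' `FALSE` with a warning.
#'
#' @inheritParams crit1_met
#' @param sg_crit2_pct Required fraction of `x_n`, in `[0, 1)`.
#'
#' @return Logical vector: `TRUE` / `FALSE` / `NA` as in [crit1_met()].
#' @export
#' @examples
#' crit2_met(40, 30, 0.25) # TRUE: drop of 10 is exactly 25% of 40
#' crit2_met(40, 31, 0.25) # FALSE
crit2_met <- function(x_n, x_n1, sg_crit2_pct = 0.25, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (!is.numeric(sg_crit2_pct) || length(sg_crit2_pct) != 1L ||
      is.na(sg_crit2_pct) || sg_crit2_pct < 0 || sg_crit2_pct >= 1) {
    stop("`sg_crit2_pct` must be a single number in [0, 1).", call. = FALSE)
  }
  change <- if (direction == "gain") x_n - x_n1 else x_n1 - x_n
  met <- change >= sg_crit2_pct * x_n
  nonpos <- !is.na(x_n) & !is.na(x_n1) & x_n <= 0
  if (any(nonpos)) {
    warning("Criterion 2 treated as not met where the pre-change score is ",
            "<= 0: a percentage change from a non-positive score is undefined.",
            call. = FALSE)
    met[nonpos] <- FALSE
  }
  met
}

#' Which points around an interval must be present
#'
#' Given the availability of the six consecutive measurements
#' `x[n-2], ..., x[n+3]` around the interval from session `n` to `n + 1`,
#' decides whether the interval can be examined for a sudden gain at all.
#' The pre-gain (`x[n]`) and post-gain (`x[n+1]`) points must always be
#' present, and at least two of the three points on each side of the
#' interval are needed to estimate the window standard deviations, so the
#' minimum number of present points is four.
#'
#' @param present Logical vector of length 6: is each of
#'   `x[n-2], x[n-1], x[n], x[n+1], x[n+2], x[n+3]` observed? Positions
#'   outside the measured session range count as missing.
#'
#' @return `TRUE` if the interval is evaluable, `FALSE` otherwise.
#' @export
#' @examples
#' pattern_evaluable(c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)) # TRUE
#' pattern_evaluable(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))  # FALSE: x_n missing
pattern_evaluable <- function(present) {
  if (length(present) != 6L || anyNA(present <- as.logical(present))) {
    stop("`present` must be six non-missing logical values, one per ",
         "position x[n-2] ... x[n+3].", call. = FALSE)
  }
  present[3L] && present[4L] &&
    sum(present[1:3]) >= 2L && sum(present[4:6]) >= 2L
}

# Core of criterion 3. pre/post are the raw windows (length <= 3, NAs allowed);
# returns the verdict plus the window statistics it was based on.
crit3_eval <- function(pre, post,
                       sg_crit3_alpha = 0.05,
                       sg_crit3_adjust = TRUE,
                       sg_crit3_critical_value = 2.776,
                       direction = "gain") {
  pre <- pre[!is.na(pre)]
  post <- post[!is.na(post)]
  n_pre <- length(pre)
  n_post <- length(post)
  out <- list(met = NA, critical_value = NA_real_,
              n_pre = n_pre, n_post = n_post,
              mean_pre = NA_real_, mean_post = NA_real_,
              sd_pre = NA_real_, sd_post = NA_real_, pooled_sd = NA_real_)
  if (n_pre < 2L || n_post < 2L) {
    return(out)
  }
  out$mean_pre <- mean(pre)
  out$mean_post <- mean(post)
  out$sd_pre <- stats::sd(pre)
  out$sd_post <- stats::sd(post)
  out$pooled_sd <- sqrt(((n_pre - 1) * out$sd_pre^2 +
                           (n_post - 1) * out$sd_post^2) /
                          (n_pre + n_post - 2))
  out$critical_value <- if (isTRUE(sg_crit3_adjust)) {
    sg_critical_value(n_pre, n_post, sg_crit3_alpha)
  } else {
    if (!is.numeric(sg_crit3_critical_value) ||
        length(sg_crit3_critical_value) != 1L ||
        is.na(sg_crit3_critical_value) || sg_crit3_critical_value <= 0) {
      stop("`sg_crit3_critical_value` must be a single positive number.",
           call. = FALSE)
    }
    sg_crit3_critical_value
  }
  diff <- if (direction == "gain") {
    out$mean_pre - out$mean_post
  } else {
    out$mean_post - out$mean_pre
  }
  # strict inequality; a degenerate zero pooled SD reduces this to a plain
  # comparison of the window means
  out$met <- diff > out$critical_value * out$pooled_sd
  out
}

#' Third criterion: change relative to local symptom fluctuation
#'
#' Tests whether the mean of the up-to-three pre-gain measurements exceeds
#' the mean of the up-to-three post-gain measurements by more than the
#' pooled standard deviation of the two windows multiplied by a critical
#' value. By default the critical value is adjusted for missing data via
#' [sg_critical_value()]; with `sg_crit3_adjust = FALSE` the fixed
#' `sg_crit3_critical_value` is applied to every interval instead.
#'
#' @param pre Pre-gain window: the available values among
#'   `x[n-2], x[n-1], x[n]` (at most 3; `NA`s are dropped).
#' @param post Post-gain window: the available values among
#'   `x[n+1], x[n+2], x[n+3]`.
#' @param sg_crit3_alpha Two-tailed alpha for the adjusted critical value.
#' @param sg_crit3_adjust Adjust the critical value to the available data
#'   pattern (default) or use `sg_crit3_critical_value` throughout?
#' @param sg_crit3_critical_value Fixed critical value used when
#'   `sg_crit3_adjust = FALSE`; default 2.776.
#' @param direction `"gain"` or `"loss"` (flips the sign of the comparison).
#'
#' @return `TRUE` / `FALSE`, or `NA` when fewer than two values are
#'   available on either side; carries the critical value that was applied
#'   in attribute `"critical_value_used"`.
#' @export
#' @examples
#' crit3_met(c(30, 29, 28), c(18, 17, 16)) # TRUE: 12 > 2.776 * 1
#' crit3_met(c(20, 20, 20), c(20, 20, 20)) # FALSE: 0 > 0 fails
crit3_met <- function(pre, post,
                      sg_crit3_alpha = 0.05,
                      sg_crit3_adjust = TRUE,
                      sg_crit3_critical_value = 2.776,
                      direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (length(pre) > 3L || length(post) > 3L) {
    stop("`pre` and `post` are windows of at most three measurements.",
         call. = FALSE)
  }
  res <- crit3_eval(pre, post,
                    sg_crit3_alpha = sg_crit3_alpha,
                    sg_crit3_adjust = sg_crit3_adjust,
                    sg_crit3_critical_value = sg_crit3_critical_value,
                    direction = direction)
  structure(res$met, critical_value_used = res$critical_value)
}

# Six-position window x[n-2] ... x[n+3] around the n -> n+1 interval,
# padded with NA outside the measured range.
window6 <- function(x, n) {
  idx <- (n - 2L):(n + 3L)
  vals <- rep(NA_real_, 6L)
  ok <- idx >= 1L & idx <= length(x)
  vals[ok] <- x[idx[ok]]
  vals
}

# Combination rule for one interval. If the Table-1 availability pattern is
# not satisfied the interval cannot be classified (NA), even when individual
# criteria were computable; otherwise every enabled criterion is computable
# and the verdict is 1 iff all are met.
combine_verdict <- function(crit1, crit2, crit3, evaluable,
                            crit2_on = TRUE, crit3_on = TRUE) {
  if (!evaluable) {
    return(NA_integer_)
  }
  verdicts <- c(crit1, if (crit2_on) crit2, if (crit3_on) crit3)
  as.integer(all(verdicts))
}

#' Examine a single session-to-session interval
#'
#' Applies the three sudden-gains (or sudden-losses) criteria to the
#' interval between sessions `n` and `n + 1` of one subject's score series
#' and reports the per-criterion verdicts, the combined classification, and
#' the window statistics behind the third criterion.
#'
#' @param x Numeric vector of one subject's scores in session order
#'   (session 1 first); `NA` for missing measurements.
#' @param n Pre-gain session index: the interval examined is `n` to `n + 1`,
#'   so `1 <= n <= length(x) - 1`.
#' @param sg_crit1_cutoff Criterion-1 cutoff in score units.
#' @param sg_crit2_pct Criterion-2 fraction; default 0.25.
#' @param sg_crit2 Apply criterion 2? Default `TRUE`.
#' @param sg_crit3 Apply criterion 3? Default `TRUE`.
#' @inheritParams crit3_met
#' @param direction `"gain"` or `"loss"`.
#'
#' @return A one-row tibble with columns `session_n`, `x_n`, `x_n1`,
#'   `sg_crit1`, `sg_crit2`, `sg_crit3` (logical, `NA` = not testable),
#'   `sg` (integer 1/0/`NA`), `n_pre`, `n_post`, and
#'   `critical_value_used`.
#' @export
#' @examples
#' x <- c(32, 31, 30, 29, 28, 18, 17, 16, 15, 14, 13, 12)
#' check_interval(x, n = 5, sg_crit1_cutoff = 7)
check_interval <- function(x, n,
                           sg_crit1_cutoff,
                           sg_crit2_pct = 0.25,
                           sg_crit2 = TRUE,
                           sg_crit3 = TRUE,
                           sg_crit3_alpha = 0.05,
                           sg_crit3_adjust = TRUE,
                           sg_crit3_critical_value = 2.776,
                           direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  x <- as.numeric(x)
  if (length(x) < 2L) {
    stop("`x` must hold at least two sessions.", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != round(n) ||
      n < 1L || n >= length(x)) {
    stop("`n` must be a pre-gain session index between 1 and ",
         length(x) - 1L, ".", call. = FALSE)
  }
  w <- window6(x, n)
  evaluable <- pattern_evaluable(!is.na(w))
  c1 <- crit1_met(w[3L], w[4L], sg_crit1_cutoff, direction)
  c2 <- if (isTRUE(sg_crit2)) {
    crit2_met(w[3L], w[4L], sg_crit2_pct, direction)
  } else {
    NA
  }
  c3res <- if (isTRUE(sg_crit3)) {
    crit3_eval(w[1:3], w[4:6],
               sg_crit3_alpha = sg_crit3_alpha,
               sg_crit3_adjust = sg_crit3_adjust,
               sg_crit3_critical_value = sg_crit3_critical_value,
               direction = direction)
  } else {
    list(met = NA, critical_value = NA_real_,
         n_pre = sum(!is.na(w[1:3])), n_post = sum(!is.na(w[4:6])))
  }
  sg <- combine_verdict(c1, c2, c3res$met, evaluable,
                        crit2_on = isTRUE(sg_crit2),
                        crit3_on = isTRUE(sg_crit3))
  tibble::tibble(
    session_n = as.integer(n),
    x_n = w[3L],
    x_n1 = w[4L],
    sg_crit1 = c1,
    sg_crit2 = c2,
    sg_crit3 = c3res$met,
    sg = sg,
    n_pre = as.integer(c3res$n_pre),
    n_post = as.integer(c3res$n_post),
    critical_value_used = c3res$critical_value
  )
}
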