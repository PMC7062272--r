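#' Reversal threshold for an identified sudden gain
#'
#' A gain counts as reversed when at least half of the improvement made
#' during the gain is lost at a later session. The threshold is therefore
#' the midpoint of the pre-gain and post-gain scores: for a drop from 40 to
#' 30 the gain has reversed once a later score of 35 or more is observed.
#'
#' @param x_n Pre-gain score (must be present).
#' @param x_n1 Post-gain score (must be present).
#'
#' @return The reversal threshold, `x_n1 + 0.5 * (x_n - x_n1)`.
#' @export
#' @examples
#' reversal_value(40, 30) # 35
reversal_value <- function(x_n, x_n1) {
  if (anyNA(x_n) || anyNA(x_n1)) {
    stop("`x_n` and `x_n1` must be present: reversal thresholds are only ",
         "defined for identified gains, where both scores exist.",
         call. = FALSE)
  }
  x_n1 + 0.5 * (x_n - x_n1)
}

#' Did a gain (or loss) reverse at a later session?
#'
#' Scans all observed scores after the post-gain session. A gain has
#' reversed if any later score reaches the threshold or more ("35 or more"
#' in the 40-to-30 example); for losses the comparison is mirrored (any
#' later score at or below the threshold).
#'
#' @param later_scores Scores at sessions `n + 2` onwards; `NA`s are
#'   skipped. An empty vector (gain at the final evaluable interval)
#'   returns `FALSE`.
#' @param threshold Reversal threshold from [reversal_value()].
#' @param direction `"gain"` or `"loss"`.
#'
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' reversal_occurred(c(31, 36, 30), 35) # TRUE
#' reversal_occurred(c(34, 30), 35)     # FALSE
reversal_occurred <- function(later_scores, threshold,
                              direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  later_scores <- later_scores[!is.na(later_scores)]
  if (length(later_scores) == 0L) {
    return(FALSE)
  }
  if (direction == "gain") {
    any(later_scores >= threshold)
  } else {
    any(later_scores <= threshold)
  }
}

# Long list of identified gains: one row per (subject row index, pre-gain
# session), ordered by subject then session.
flagged_gains <- function(flags, id_var_name, direction) {
  prefix <- if (direction == "gain") "sg_" else "sl_"
  comb_cols <- grep(paste0("^", prefix, "[0-9]+to[0-9]+$"), names(flags),
                    value = TRUE)
  sessions <- as.integer(sub("to.*$", "", sub(paste0("^", prefix), "",
                                              comb_cols)))
  rows <- integer(0)
  ns <- integer(0)
  for (i in seq_len(nrow(flags))) {
    hit <- which(!is.na(as.integer(unlist(flags[i, comb_cols]))) &
                   as.integer(unlist(flags[i, comb_cols])) == 1L)
    if (length(hit) > 0L) {
      rows <- c(rows, rep(i, length(hit)))
      ns <- c(ns, sessions[hit])
    }
  }
  list(row = rows, session_n = ns)
}

empty_bysg_schema <- function(id_var_name, sg_measure_name, data_cols) {
  out <- tibble::tibble(
    id_sg = character(0),
    !!id_var_name := vector(mode = "character", length = 0),
    sg_crit123 = integer(0),
    sg_session_n = integer(0),
    sg_freq_byperson = integer(0)
  )
  for (pos in c("2n", "1n", "n", "n1", "n2", "n3")) {
    out[[paste0("sg_", sg_measure_name, "_", pos)]] <- numeric(0)
  }
  out$sg_magnitude <- numeric(0)
  out[[paste0("sg_", sg_measure_name, "_tx_change")]] <- numeric(0)
  out$sg_change_proportion <- numeric(0)
  out$sg_reversal_value <- numeric(0)
  out$sg_reversal <- integer(0)
  for (col in data_cols) out[[col]] <- numeric(0)
  out
}

build_gain_records <- function(data, flags, id_var_name, sg_var_list,
                               tx_start_var_name, tx_end_var_name,
                               sg_measure_name, direction) {
  m <- wide_score_matrix(data, id_var_name, sg_var_list)
  ids <- data[[id_var_name]]
  hits <- flagged_gains(flags, id_var_name, direction)
  keep_cols <- union(sg_var_list,
                     intersect(c(tx_start_var_name, tx_end_var_name),
                               names(data)))
  if (length(hits$row) == 0L) {
    out <- empty_bysg_schema(id_var_name, sg_measure_name, keep_cols)
    out[[id_var_name]] <- ids[0]
    return(out)
  }
  ord <- order(hits$row, hits$session_n)
  row_i <- hits$row[ord]
  n_i <- hits$session_n[ord]
  freq <- table(row_i)
  tag <- if (direction == "gain") "_sg" else "_sl"

  x_n <- m[cbind(row_i, n_i)]
  x_n1 <- m[cbind(row_i, n_i + 1L)]
  magnitude <- if (direction == "gain") x_n - x_n1 else x_n1 - x_n
  tx_start <- as.numeric(data[[tx_start_var_name]][row_i])
  tx_end <- as.numeric(data[[tx_end_var_name]][row_i])
  # signed so that the clinically expected direction is positive:
  # improvement (start - end) for gains, deterioration (end - start) for losses
  tx_change <- if (direction == "gain") tx_start - tx_end else tx_end - tx_start
  proportion <- ifelse(!is.na(tx_change) & tx_change > 0,
                       magnitude / tx_change, NA_real_)
  if (any(!is.na(tx_change) & tx_change <= 0)) {
    warning("sg_change_proportion set to NA where the total treatment ",
            "change is zero or in the unexpected direction.", call. = FALSE)
  }
  rev_value <- reversal_value(x_n, x_n1)
  rev_flag <- vapply(seq_along(row_i), function(k) {
    later <- if (n_i[k] + 2L <= ncol(m)) {
      m[row_i[k], (n_i[k] + 2L):ncol(m)]
    } else {
      numeric(0)
    }
    reversal_occurred(later, rev_value[k], direction)
  }, logical(1))

  out <- tibble::tibble(
    id_sg = paste0(ids[row_i], tag, n_i),
    !!id_var_name := ids[row_i],
    sg_crit123 = 1L,
    sg_session_n = as.integer(n_i),
    sg_freq_byperson = as.integer(freq[as.character(row_i)])
  )
  around <- vapply(-2:3, function(off) {
    idx <- n_i + off
    val <- rep(NA_real_, length(n_i))
    ok <- idx >= 1L & idx <= ncol(m)
    val[ok] <- m[cbind(row_i[ok], idx[ok])]
    val
  }, numeric(length(n_i)))
  around <- matrix(around, nrow = length(n_i))
  pos_labels <- c("2n", "1n", "n", "n1", "n2", "n3")
  for (j in seq_along(pos_labels)) {
    out[[paste0("sg_", sg_measure_name, "_", pos_labels[j])]] <- around[, j]
  }
  out$sg_magnitude <- magnitude
  out[[paste0("sg_", sg_measure_name, "_tx_change")]] <- tx_change
  out$sg_change_proportion <- proportion
  out$sg_reversal_value <- rev_value
  out$sg_reversal <- as.integer(rev_flag)
  for (col in keep_cols) out[[col]] <- as.numeric(data[[col]][row_i])
  out
}

#' Create the one-row-per-gain (bysg) analysis dataset
#'
#' Identifies sudden gains (or losses) and builds a dataset with one row
#' per identified gain, carrying the around-gain scores `N-2 ... N+3`, the
#' raw gain magnitude, the share of the total treatment change the gain
#' accounts for, the reversal threshold and whether it was reached later,
#' plus the subject's raw session scores for further analysis.
#'
#' @inheritParams identify_sg
#' @param tx_start_var_name,tx_end_var_name Columns holding the scores at
#'   the start and end of treatment (used for the total-change variables).
#' @param sg_measure_name Short measure label embedded in the new variable
#'   names (e.g. `"bdi"` produces `sg_bdi_n`, `sg_bdi_tx_change`).
#' @param identify Identify `"sg"` (sudden gains, default) or `"sl"`
#'   (sudden losses). For losses `sg_magnitude` is the increase
#'   `x[n+1] - x[n]` and the total-change variable is end minus start, so
#'   both remain positive in the clinically expected direction.
#'
#' @return A tibble with one row per identified gain and columns `id_sg`,
#'   the id column, `sg_crit123`, `sg_session_n`, `sg_freq_byperson`,
#'   `sg_<measure>_2n` ... `sg_<measure>_n3`, `sg_magnitude`,
#'   `sg_<measure>_tx_change`, `sg_change_proportion`,
#'   `sg_reversal_value`, `sg_reversal`, and the raw session columns.
#'   A dataset with no gains keeps the full schema with zero rows.
#' @seealso [create_byperson()], [extract_values()], [describe_sg()]
#' @export
#' @examples
#' demo <- sg_demo_data()
#' bysg <- create_bysg(demo,
#'   id_var_name = "id",
#'   tx_start_var_name = "bdi_s1", tx_end_var_name = "bdi_s12",
#'   sg_var_list = expand_var_range("bdi_s1:bdi_s12"),
#'   sg_crit1_cutoff = 7, sg_measure_name = "bdi"
#' )
#' nrow(bysg)
create_bysg <- function(data, id_var_name, sg_var_list,
                        tx_start_var_name, tx_end_var_name,
                        sg_crit1_cutoff = 7,
                        sg_crit2_pct = 0.25,
                        sg_crit2 = TRUE,
                        sg_crit3 = TRUE,
                        sg_crit3_alpha = 0.05,
                        sg_crit3_adjust = TRUE,
                        sg_crit3_critical_value = 2.776,
                        sg_measure_name = "sg",
                        identify = c("sg", "sl")) {
  identify <- match.arg(identify)
  direction <- if (identify == "sg") "gain" else "loss"
  missing_tx <- setdiff(c(tx_start_var_name, tx_end_var_name), names(data))
  if (length(missing_tx) > 0L) {
    stop("Treatment start/end column(s) not found in `data`: ",
         paste(missing_tx, collapse = ", "), call. = FALSE)
  }
  flags <- identify_impl(data, id_var_name, sg_var_list,
                         sg_crit1_cutoff, sg_crit2_pct, sg_crit2,
                         sg_crit3, sg_crit3_alpha, sg_crit3_adjust,
                         sg_crit3_critical_value,
                         direction = direction, crit123_details = FALSE)
  out <- build_gain_records(data, flags, id_var_name, sg_var_list,
                            tx_start_var_name, tx_end_var_name,
                            sg_measure_name, direction)
  attr(out, "sg_measure_name") <- sg_measure_name
  attr(out, "sg_n_sessions") <- length(sg_var_list)
  attr(out, "sg_direction") <- direction
  attr(out, "sg_tx_vars") <- c(tx_start_var_name, tx_end_var_name)
  out
}

#' Create the one-row-per-person (byperson) analysis dataset
#'
#' Builds a dataset with one row per subject, whether or not they
#' experienced a sudden gain. Subjects without a gain get `sg_crit123 = 0`
#' and missing gain-specific fields. For subjects with several gains, the
#' gain described on their row is chosen by `multiple_sg_select`.
#'
#' @inheritParams create_bysg
#' @param multiple_sg_select Which gain represents a multi-gain subject:
#'   `"first"` (earliest pre-gain session, default), `"last"`,
#'   `"smallest"` or `"largest"` (by `sg_magnitude`; ties broken by the
#'   earlier session).
#'
#' @return A tibble with one row per subject in the original row order and
#'   the same gain columns as [create_bysg()].
#' @export
create_byperson <- function(data, id_var_name, sg_var_list,
                            tx_start_var_name, tx_end_var_name,
                            sg_crit1_cutoff = 7,
                            sg_crit2_pct = 0.25,
                            sg_crit2 = TRUE,
                            sg_crit3 = TRUE,
                            sg_crit3_alpha = 0.05,
                            sg_crit3_adjust = TRUE,
                            sg_crit3_critical_value = 2.776,
                            sg_measure_name = "sg",
                            identify = c("sg", "sl"),
                            multiple_sg_select = c("first", "last",
                                                   "smallest", "largest")) {
  multiple_sg_select <- match.arg(multiple_sg_select)
  identify <- match.arg(identify)
  bysg <- create_bysg(data, id_var_name, sg_var_list,
                      tx_start_var_name, tx_end_var_name,
                      sg_crit1_cutoff = sg_crit1_cutoff,
                      sg_crit2_pct = sg_crit2_pct,
                      sg_crit2 = sg_crit2,
                      sg_crit3 = sg_crit3,
                      sg_crit3_alpha = sg_crit3_alpha,
                      sg_crit3_adjust = sg_crit3_adjust,
                      sg_crit3_critical_value = sg_crit3_critical_value,
                      sg_measure_name = sg_measure_name,
                      identify = identify)
  ids <- data[[id_var_name]]
  sel_rows <- integer(nrow(data))
  for (i in seq_along(ids)) {
    k <- which(bysg[[id_var_name]] == ids[i])
    if (length(k) == 0L) {
      sel_rows[i] <- NA_integer_
      next
    }
    sel_rows[i] <- switch(
      multiple_sg_select,
      first = k[which.min(bysg$sg_session_n[k])],
      last = k[which.max(bysg$sg_session_n[k])],
      smallest = k[order(bysg$sg_magnitude[k], bysg$sg_session_n[k])[1L]],
      largest = k[order(-bysg$sg_magnitude[k], bysg$sg_session_n[k])[1L]]
    )
  }
  gain_cols <- setdiff(names(bysg), id_var_name)
  out <- tibble::tibble(!!id_var_name := ids)
  for (col in gain_cols) {
    template <- bysg[[col]]
    vals <- template[sel_rows]
    out[[col]] <- vals
  }
  # non-gainers: crit123 is a definite 0 and their raw data are retained
  none <- is.na(sel_rows)
  out$sg_crit123[none] <- 0L
  out$sg_freq_byperson[none] <- 0L
  keep_cols <- union(sg_var_list,
                     intersect(c(tx_start_var_name, tx_end_var_name),
                               names(data)))
  for (col in keep_cols) {
    out[[col]][none] <- as.numeric(data[[col]][none])
  }
  out <- out[, c("id_sg", id_var_name,
                 setdiff(names(out), c("id_sg", id_var_name)))]
  attr(out, "sg_measure_name") <- sg_measure_name
  attr(out, "sg_n_sessions") <- length(sg_var_list)
  attr(out, "sg_direction") <- if (identify == "sg") "gain" else "loss"
  attr(out, "sg_select") <- multiple_sg_select
  attr(out, "sg_tx_vars") <- c(tx_start_var_name, tx_end_var_name)
  out
}

#' Extract a secondary measure around each sudden gain
#'
#' For each identified gain (each row with a non-missing `sg_session_n`),
#' pulls the scores of a second, parallel measure at the same absolute
#' sessions `N-2 ... N+3` as the gain, creating columns
#' `sg_<measure>_2n` ... `sg_<measure>_n3`. The secondary columns must be
#' measured at the same timepoints as the primary series used to identify
#' the gains, so their count must match.
#'
#' @param data A bysg or byperson dataset that already contains the
#'   secondary measure columns (e.g. after a join by id).
#' @param id_var_name Name of the identifier column (`"id_sg"` for bysg).
#' @param extract_var_list Secondary measure columns in session order; must
#'   have one column per session of the primary series.
#' @param extract_measure_name Label for the new columns (e.g. `"rq"`).
#' @param add_to_data Return `data` with the new columns appended
#'   (default), or only the id column plus the new columns?
#'
#' @return A tibble; positions outside the measured range are `NA`, as are
#'   all six values for rows without a gain.
#' @export
extract_values <- function(data, id_var_name, extract_var_list,
                           extract_measure_name, add_to_data = TRUE) {
  missing_cols <- setdiff(c(id_var_name, extract_var_list, "sg_session_n"),
                          names(data))
  if (length(missing_cols) > 0L) {
    stop("Column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_sessions <- attr(data, "sg_n_sessions")
  if (!is.null(n_sessions) && length(extract_var_list) != n_sessions) {
    stop("`extract_var_list` has ", length(extract_var_list),
         " columns but the gains were identified over ", n_sessions,
         " sessions; the secondary measure must be measured at the same ",
         "timepoints as the primary series.", call. = FALSE)
  }
  m <- as.matrix(data.frame(lapply(data[extract_var_list], as.numeric)))
  n_i <- as.integer(data$sg_session_n)
  pos_labels <- c("2n", "1n", "n", "n1", "n2", "n3")
  new_cols <- tibble::tibble(!!id_var_name := data[[id_var_name]])
  for (j in seq_along(pos_labels)) {
    off <- (-2:3)[j]
    idx <- n_i + off
    val <- rep(NA_real_, nrow(data))
    ok <- !is.na(idx) & idx >= 1L & idx <= length(extract_var_list)
    val[ok] <- m[cbind(which(ok), idx[ok])]
    new_cols[[paste0("sg_", extract_measure_name, "_", pos_labels[j])]] <- val
  }
  if (isTRUE(add_to_data)) {
    out <- dplyr::bind_cols(data, new_cols[-1L])
    for (a in c("sg_measure_name", "sg_n_sessions", "sg_direction",
                "sg_select", "sg_tx_vars")) {
      attr(out, a) <- attr(data, a)
    }
    out
  } else {
    new_cols
  }
}
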