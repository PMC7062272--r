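#' Descriptive summary of identified sudden gains
#'
#' Combines the gain-level (bysg) and person-level (byperson) datasets into
#' one summary row: how many subjects gained, how many more than once, the
#' total number of gains, their mean magnitude and pre-gain session, and
#' how many reversed.
#'
#' @param bysg Dataset from [create_bysg()].
#' @param byperson Dataset from [create_byperson()] built with the same
#'   measure and settings.
#'
#' @return A one-row tibble with columns `n_subjects`, `n_gainers`,
#'   `pct_gainers` (fraction of subjects), `n_multigainers`, `total_gains`,
#'   `mean_magnitude`, `sd_magnitude`, `n_reversed`, `pct_reversed`
#'   (fraction of gains) and `mean_session_n`. With no gains the counts
#'   are 0 and the means `NA`.
#' @export
#' @examples
#' demo <- sg_demo_data()
#' vars <- expand_var_range("bdi_s1:bdi_s12")
#' bysg <- create_bysg(demo, "id", vars, "bdi_s1", "bdi_s12",
#'                     sg_crit1_cutoff = 7, sg_measure_name = "bdi")
#' byp <- create_byperson(demo, "id", vars, "bdi_s1", "bdi_s12",
#'                        sg_crit1_cutoff = 7, sg_measure_name = "bdi")
#' describe_sg(bysg, byp)
describe_sg <- function(bysg, byperson) {
  m1 <- attr(bysg, "sg_measure_name")
  m2 <- attr(byperson, "sg_measure_name")
  if (!is.null(m1) && !is.null(m2) && !identical(m1, m2)) {
    stop("`bysg` and `byperson` were built for different measures (\"",
         m1, "\" vs \"", m2, "\").", call. = FALSE)
  }
  needed_bysg <- c("sg_magnitude", "sg_session_n", "sg_reversal")
  if (!all(needed_bysg %in% names(bysg))) {
    stop("`bysg` does not look like a create_bysg() dataset.", call. = FALSE)
  }
  if (!"sg_crit123" %in% names(byperson)) {
    stop("`byperson` does not look like a create_byperson() dataset.",
         call. = FALSE)
  }
  n_subjects <- nrow(byperson)
  n_gainers <- sum(byperson$sg_crit123 == 1L, na.rm = TRUE)
  total_gains <- nrow(bysg)
  # distinct subjects with two or more gains; the id column is the second
  # column of every bysg dataset
  n_multi <- if (total_gains > 0L) {
    length(unique(bysg[[2L]][bysg$sg_freq_byperson >= 2L]))
  } else {
    0L
  }
  tibble::tibble(
    n_subjects = n_subjects,
    n_gainers = as.integer(n_gainers),
    pct_gainers = if (n_subjects > 0L) n_gainers / n_subjects else NA_real_,
    n_multigainers = as.integer(n_multi),
    total_gains = as.integer(total_gains),
    mean_magnitude = if (total_gains > 0L) mean(bysg$sg_magnitude) else NA_real_,
    sd_magnitude = if (total_gains > 1L) stats::sd(bysg$sg_magnitude) else NA_real_,
    n_reversed = as.integer(sum(bysg$sg_reversal == 1L, na.rm = TRUE)),
    pct_reversed = if (total_gains > 0L) {
      sum(bysg$sg_reversal == 1L, na.rm = TRUE) / total_gains
    } else {
      NA_real_
    },
    mean_session_n = if (total_gains > 0L) mean(bysg$sg_session_n) else NA_real_
  )
}

#' Average score profile around the sudden gain
#'
#' Aggregates the six around-gain positions `N-2 ... N+3` over all
#' identified gains: per-position mean, standard deviation, and the number
#' of gains contributing (missing values are excluded position-wise). When
#' the dataset carries treatment start/end columns, their means are
#' appended as `tx_start` / `tx_end` anchor rows.
#'
#' @param bysg Dataset from [create_bysg()] (or a byperson dataset
#'   restricted to gainers).
#' @param sg_measure_name Measure label used in the around-gain column
#'   names; defaults to the label the dataset was built with.
#'
#' @return A tibble with columns `position` (ordered factor
#'   `tx_start, 2n, 1n, n, n1, n2, n3, tx_end` as available), `mean`,
#'   `sd` and `n`.
#' @export
average_gain_profile <- function(bysg, sg_measure_name = NULL) {
  if (is.null(sg_measure_name)) {
    sg_measure_name <- attr(bysg, "sg_measure_name")
  }
  if (is.null(sg_measure_name)) {
    stop("`sg_measure_name` must be given when `bysg` does not carry one.",
         call. = FALSE)
  }
  pos_labels <- c("2n", "1n", "n", "n1", "n2", "n3")
  cols <- paste0("sg_", sg_measure_name, "_", pos_labels)
  missing_cols <- setdiff(cols, names(bysg))
  if (length(missing_cols) > 0L) {
    stop("Around-gain column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(bysg) == 0L) {
    stop("`bysg` holds no gains; there is no profile to average.",
         call. = FALSE)
  }
  rows <- lapply(seq_along(cols), function(j) {
    v <- bysg[[cols[j]]]
    v <- v[!is.na(v)]
    tibble::tibble(position = pos_labels[j],
                   mean = if (length(v) > 0L) mean(v) else NA_real_,
                   sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                   n = length(v))
  })
  out <- dplyr::bind_rows(rows)
  tx_vars <- attr(bysg, "sg_tx_vars")
  levels <- pos_labels
  if (!is.null(tx_vars) && all(tx_vars %in% names(bysg))) {
    anchor <- function(col, label) {
      v <- bysg[[col]]
      v <- v[!is.na(v)]
      tibble::tibble(position = label,
                     mean = if (length(v) > 0L) mean(v) else NA_real_,
                     sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                     n = length(v))
    }
    out <- dplyr::bind_rows(anchor(tx_vars[1L], "tx_start"), out,
                            anchor(tx_vars[2L], "tx_end"))
    levels <- c("tx_start", pos_labels, "tx_end")
  }
  out$position <- factor(out$position, levels = levels, ordered = TRUE)
  out
}

#' Long-format trajectories for plotting
#'
#' Reshapes selected subjects' session scores into a long table
#' (id, session, value), ordered by subject and session -- the input for a
#' spaghetti plot of individual trajectories.
#'
#' @inheritParams identify_sg
#' @param select_id_list Ids to include; `NULL` (default) keeps every
#'   subject. Unknown ids raise an error naming them. To select by a
#'   condition (e.g. every subject with a gain between sessions 3 and 4),
#'   filter a flag or bysg table first and pass its ids.
#'
#' @return A tibble with columns `<id_var_name>`, `session` (integer) and
#'   `value`.
#' @export
trajectory_data <- function(data, id_var_name, sg_var_list,
                            select_id_list = NULL) {
  m <- wide_score_matrix(data, id_var_name, sg_var_list)
  ids <- data[[id_var_name]]
  if (!is.null(select_id_list)) {
    unknown <- setdiff(select_id_list, ids)
    if (length(unknown) > 0L) {
      stop("Id(s) not found in `data`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- match(select_id_list, ids)
  } else {
    keep <- seq_along(ids)
  }
  if (length(keep) == 0L) {
    return(tibble::tibble(!!id_var_name := ids[0],
                          session = integer(0), value = numeric(0)))
  }
  s <- length(sg_var_list)
  tibble::tibble(
    !!id_var_name := rep(ids[keep], each = s),
    session = rep(seq_len(s), times = length(keep)),
    value = as.vector(t(m[keep, , drop = FALSE]))
  )
}

#' Plot the average sudden gain
#'
#' Line plot of the mean score at the six around-gain positions (with a
#' +/- 1 SD ribbon), optionally split by a grouping column of the bysg
#' dataset (e.g. a trial arm).
#'
#' @inheritParams average_gain_profile
#' @param group_var_name Optional bysg column to facet the averages by.
#' @param ylab Y axis label; defaults to the measure label.
#'
#' @return A ggplot object.
#' @export
plot_sg <- function(bysg, sg_measure_name = NULL, group_var_name = NULL,
                    ylab = NULL) {
  if (is.null(sg_measure_name)) {
    sg_measure_name <- attr(bysg, "sg_measure_name")
  }
  if (is.null(group_var_name)) {
    prof <- average_gain_profile(bysg, sg_measure_name)
    prof$group <- "all"
  } else {
    if (!group_var_name %in% names(bysg)) {
      stop("Grouping column `", group_var_name, "` not found.", call. = FALSE)
    }
    groups <- split(seq_len(nrow(bysg)), bysg[[group_var_name]])
    prof <- dplyr::bind_rows(lapply(names(groups), function(g) {
      sub <- bysg[groups[[g]], , drop = FALSE]
      for (a in c("sg_measure_name", "sg_tx_vars")) {
        attr(sub, a) <- attr(bysg, a)
      }
      p <- average_gain_profile(sub, sg_measure_name)
      p$group <- g
      p
    }))
  }
  prof <- prof[prof$position %in% c("2n", "1n", "n", "n1", "n2", "n3"), ]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$mean,
                                     group = .data$group,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Session relative to the gain",
                  y = ylab %||% toupper(sg_measure_name),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot individual score trajectories
#'
#' Spaghetti plot of selected subjects' session-by-session scores.
#'
#' @inheritParams trajectory_data
#' @param ylab Y axis label.
#'
#' @return A ggplot object.
#' @export
plot_sg_trajectories <- function(data, id_var_name, sg_var_list,
                                 select_id_list = NULL, ylab = "Score") {
  long <- trajectory_data(data, id_var_name, sg_var_list, select_id_list)
  long$.id <- factor(long[[id_var_name]])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$session, y = .data$value,
                                     group = .data$.id,
                                     colour = .data$.id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_continuous(breaks = seq_along(sg_var_list)) +
    ggplot2::labs(x = "Session", y = ylab, colour = id_var_name) +
    ggplot2::theme_minimal()
}
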