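# Shared validation for wide datasets: id column present and unique, all
# session columns present and numeric. Returns the numeric score matrix.
wide_score_matrix <- function(data, id_var_name, sg_var_list,
                              min_sessions = 4L) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame in wide format.", call. = FALSE)
  }
  missing_cols <- setdiff(c(id_var_name, sg_var_list), names(data))
  if (length(missing_cols) > 0L) {
    stop("Column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(sg_var_list) < min_sessions) {
    stop("`sg_var_list` must name at least ", min_sessions,
         " session columns; fewer leave no evaluable interval.",
         call. = FALSE)
  }
  ids <- data[[id_var_name]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("Duplicate values in id column `", id_var_name, "`: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  scores <- data[sg_var_list]
  not_numeric <- names(scores)[!vapply(scores, function(col) {
    is.numeric(col) || inherits(col, "haven_labelled")
  }, logical(1))]
  if (length(not_numeric) > 0L) {
    stop("Session column(s) are not numeric: ",
         paste(not_numeric, collapse = ", "), call. = FALSE)
  }
  m <- vapply(scores, function(col) as.numeric(col), numeric(nrow(data)))
  m <- matrix(m, nrow = nrow(data),
              dimnames = list(NULL, sg_var_list))
  m
}

# Sweep every evaluable interval (pre-gain sessions 2 ... S-2) of every
# subject. Returns the flag table plus a log of intervals that could not be
# classified and which mandatory points were missing there.
identify_impl <- function(data, id_var_name, sg_var_list,
                          sg_crit1_cutoff, sg_crit2_pct, sg_crit2,
                          sg_crit3, sg_crit3_alpha, sg_crit3_adjust,
                          sg_crit3_critical_value,
                          direction, crit123_details) {
  m <- wide_score_matrix(data, id_var_name, sg_var_list)
  s <- ncol(m)
  pregain <- 2L:(s - 2L)
  prefix <- if (direction == "gain") "sg" else "sl"
  out <- tibble::tibble(!!id_var_name := data[[id_var_name]])
  log_id <- character(0)
  log_interval <- character(0)
  log_missing <- character(0)
  pos_names <- c("x_n-2", "x_n-1", "x_n", "x_n+1", "x_n+2", "x_n+3")

  for (n in pregain) {
    lab <- paste0(n, "to", n + 1L)
    c1 <- c2 <- c3 <- rep(NA, nrow(m))
    comb <- rep(NA_integer_, nrow(m))
    for (i in seq_len(nrow(m))) {
      w <- window6(m[i, ], n)
      avail <- !is.na(w)
      evaluable <- pattern_evaluable(avail)
      c1[i] <- crit1_met(w[3L], w[4L], sg_crit1_cutoff, direction)
      if (isTRUE(sg_crit2)) {
        c2[i] <- crit2_met(w[3L], w[4L], sg_crit2_pct, direction)
      }
      if (isTRUE(sg_crit3)) {
        c3[i] <- crit3_eval(w[1:3], w[4:6],
                            sg_crit3_alpha = sg_crit3_alpha,
                            sg_crit3_adjust = sg_crit3_adjust,
                            sg_crit3_critical_value = sg_crit3_critical_value,
                            direction = direction)$met
      }
      comb[i] <- combine_verdict(c1[i], c2[i], c3[i], evaluable,
                                 crit2_on = isTRUE(sg_crit2),
                                 crit3_on = isTRUE(sg_crit3))
      if (!evaluable) {
        need <- c(!avail[3L], !avail[4L],
                  sum(avail[1:3]) < 2L, sum(avail[4:6]) < 2L)
        why <- c(pos_names[3L], pos_names[4L],
                 "fewer than 2 of x_n-2..x_n",
                 "fewer than 2 of x_n+1..x_n+3")[need]
        log_id <- c(log_id, as.character(data[[id_var_name]][i]))
        log_interval <- c(log_interval, lab)
        log_missing <- c(log_missing, paste(why, collapse = "; "))
      }
    }
    if (isTRUE(crit123_details)) {
      out[[paste0(prefix, "_crit1_", lab)]] <- c1
      out[[paste0(prefix, "_crit2_", lab)]] <- c2
      out[[paste0(prefix, "_crit3_", lab)]] <- c3
    }
    out[[paste0(prefix, "_", lab)]] <- comb
  }
  attr(out, "sg_missing_log") <- tibble::tibble(
    id = log_id, interval = log_interval, missing = log_missing
  )
  attr(out, "sg_direction") <- direction
  out
}

#' Identify sudden gains across a wide-format dataset
#'
#' Applies the three sudden-gains criteria to every session-to-session
#' interval of every subject. Intervals whose pre-gain session is 1 or
#' `S - 1` (for `S` sessions) are omitted: the required data pattern around
#' them can never be satisfied. The first evaluable interval for a
#' 12-session series is therefore `sg_2to3` and the last `sg_10to11`.
#'
#' @param data Wide-format data frame: one row per subject, one column per
#'   session score.
#' @param id_var_name Name of the unique subject identifier column.
#' @param sg_var_list Character vector of session score column names in
#'   session order (see [expand_var_range()] for a `"bdi_s1:bdi_s12"`
#'   shorthand).
#' @param sg_crit1_cutoff Criterion-1 cutoff in score units (default 7,
#'   the classic BDI value; see [define_crit1_cutoff()] for other scales).
#' @param sg_crit2_pct Criterion-2 fraction of the pre-gain score
#'   (default 0.25).
#' @param sg_crit2 Apply criterion 2? Default `TRUE`.
#' @param sg_crit3 Apply criterion 3? Default `TRUE`.
#' @param sg_crit3_alpha Alpha for the adjusted criterion-3 critical value.
#' @param sg_crit3_adjust Adjust the criterion-3 critical value to the
#'   available data pattern (default) or apply
#'   `sg_crit3_critical_value` to every interval?
#' @param sg_crit3_critical_value Fixed critical value used when
#'   `sg_crit3_adjust = FALSE`.
#' @param crit123_details Also emit the per-criterion `TRUE`/`FALSE`/`NA`
#'   columns (`sg_crit1_2to3`, ...)?
#'
#' @return A tibble with the id column and, per interval, an integer column
#'   `sg_<n>to<n+1>` holding 1 (sudden gain), 0 (no gain) or `NA` (not
#'   classifiable from the available data). With `crit123_details = TRUE`
#'   the logical per-criterion columns precede each combined column.
#'   Attribute `"sg_missing_log"` records, for every unclassifiable
#'   interval, which required points were missing.
#' @seealso [identify_sl()], [check_interval()], [create_bysg()]
#' @export
#' @examples
#' demo <- sg_demo_data()
#' flags <- identify_sg(demo,
#'   id_var_name = "id",
#'   sg_var_list = expand_var_range("bdi_s1:bdi_s12"),
#'   sg_crit1_cutoff = 7
#' )
#' colSums(flags[-1] == 1, na.rm = TRUE)
identify_sg <- function(data, id_var_name, sg_var_list,
                        sg_crit1_cutoff = 7,
                        sg_crit2_pct = 0.25,
                        sg_crit2 = TRUE,
                        sg_crit3 = TRUE,
                        sg_crit3_alpha = 0.05,
                        sg_crit3_adjust = TRUE,
                        sg_crit3_critical_value = 2.776,
                        crit123_details = FALSE) {
  identify_impl(data, id_var_name, sg_var_list,
                sg_crit1_cutoff, sg_crit2_pct, sg_crit2,
                sg_crit3, sg_crit3_alpha, sg_crit3_adjust,
                sg_crit3_critical_value,
                direction = "gain", crit123_details = crit123_details)
}

#' Identify sudden losses
#'
#' Identical to [identify_sg()] but applies the criteria in the inverse
#' direction: a sudden loss is a large, stable session-to-session
#' deterioration. Some studies raise the criterion-2 percentage for losses
#' (e.g. `sg_crit2_pct = 0.33`); the default keeps 0.25.
#'
#' @inheritParams identify_sg
#' @return As [identify_sg()], with columns named `sl_<n>to<n+1>`.
#' @export
identify_sl <- function(data, id_var_name, sg_var_list,
                        sg_crit1_cutoff = 7,
                        sg_crit2_pct = 0.25,
                        sg_crit2 = TRUE,
                        sg_crit3 = TRUE,
                        sg_crit3_alpha = 0.05,
                        sg_crit3_adjust = TRUE,
                        sg_crit3_critical_value = 2.776,
                        crit123_details = FALSE) {
  identify_impl(data, id_var_name, sg_var_list,
                sg_crit1_cutoff, sg_crit2_pct, sg_crit2,
                sg_crit3, sg_crit3_alpha, sg_crit3_adjust,
                sg_crit3_critical_value,
                direction = "loss", crit123_details = crit123_details)
}

#' Select cases whose data permit a sudden-gains analysis
#'
#' Flags subjects for inclusion either because at least one
#' session-to-session interval satisfies the minimum data pattern
#' (`method = "pattern"`), or because at least `min_sess_num` sessions are
#' observed (`method = "min_sess"`).
#'
#' @inheritParams identify_sg
#' @param method `"pattern"` (default) or `"min_sess"`.
#' @param min_sess_num Minimum number of observed sessions; required when
#'   `method = "min_sess"`.
#'
#' @return A tibble with the id column and a logical `sg_select` column.
#' @export
select_cases <- function(data, id_var_name, sg_var_list,
                         method = c("pattern", "min_sess"),
                         min_sess_num = NULL) {
  method <- match.arg(method)
  m <- wide_score_matrix(data, id_var_name, sg_var_list)
  s <- ncol(m)
  include <- if (method == "pattern") {
    apply(m, 1L, function(x) {
      any(vapply(2L:(s - 2L), function(n) {
        pattern_evaluable(!is.na(window6(x, n)))
      }, logical(1)))
    })
  } else {
    if (is.null(min_sess_num) || !is.numeric(min_sess_num) ||
        length(min_sess_num) != 1L || is.na(min_sess_num) ||
        min_sess_num < 1 || min_sess_num > s) {
      stop("`min_sess_num` must be a single number between 1 and ", s,
           " when method = \"min_sess\".", call. = FALSE)
    }
    rowSums(!is.na(m)) >= min_sess_num
  }
  tibble::tibble(!!id_var_name := data[[id_var_name]],
                 sg_select = unname(include))
}
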