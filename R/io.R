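#' Expand a session-column range shorthand
#'
#' Turns `"bdi_s1:bdi_s12"` into `c("bdi_s1", ..., "bdi_s12")`. Both ends
#' must share the same prefix and end in an integer.
#'
#' @param range A single string `"<prefix><from>:<prefix><to>"`.
#'
#' @return Character vector of column names.
#' @export
#' @examples
#' expand_var_range("bdi_s1:bdi_s12")
expand_var_range <- function(range) {
  if (!is.character(range) || length(range) != 1L || !grepl(":", range)) {
    stop("`range` must be a single string like \"bdi_s1:bdi_s12\".",
         call. = FALSE)
  }
  ends <- strsplit(range, ":", fixed = TRUE)[[1L]]
  if (length(ends) != 2L) {
    stop("`range` must contain exactly one ':'.", call. = FALSE)
  }
  m <- regmatches(ends, regexec("^(.*?)([0-9]+)$", ends))
  if (any(lengths(m) != 3L)) {
    stop("Both ends of `range` must end in an integer.", call. = FALSE)
  }
  prefix <- vapply(m, `[`, character(1), 2L)
  nums <- as.integer(vapply(m, `[`, character(1), 3L))
  if (prefix[1L] != prefix[2L]) {
    stop("Both ends of `range` must share the same prefix (got \"",
         prefix[1L], "\" and \"", prefix[2L], "\").", call. = FALSE)
  }
  paste0(prefix[1L], seq(nums[1L], nums[2L]))
}

format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("csv", "tsv", "sav", "dta", "xlsx")) {
    stop("Unsupported file extension `.", ext,
         "`; use .csv, .tsv, .sav, .dta or .xlsx.", call. = FALSE)
  }
  ext
}

#' Read a wide-format dataset
#'
#' Reads CSV/TSV (empty cells and literal `NA` become missing), SPSS
#' `.sav`, Stata `.dta`, or Excel `.xlsx` files into a tibble, picking the
#' reader from the file extension.
#'
#' @param path File path.
#' @param format Override the extension-derived format
#'   (`"csv"`, `"tsv"`, `"sav"`, `"dta"`, `"xlsx"`).
#'
#' @return A tibble.
#' @export
read_sg_data <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  format <- format %||% format_from_path(path)
  switch(format,
    csv = readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE),
    tsv = readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE),
    sav = haven::read_sav(path),
    dta = haven::read_dta(path),
    xlsx = readxl::read_excel(path),
    stop("Unsupported format: ", format, call. = FALSE)
  )
}

# variable labels embedded in .sav/.dta exports
sg_variable_labels <- c(
  id_sg = "Unique ID variable for every identified sudden gain / loss",
  sg_crit123 = "Whether all applied sudden gain criteria were met (No = 0; Yes = 1)",
  sg_session_n = "Pregain session number",
  sg_freq_byperson = "Frequency of sudden gains / losses per person",
  sg_magnitude = "Raw magnitude of sudden gain",
  sg_change_proportion = "Proportion of total change represented by the sudden gain",
  sg_reversal_value = "Reversal value",
  sg_reversal = "Whether the reversal value was met after the gain (No = 0; Yes = 1)"
)

write_sg_data <- function(data, path, format = NULL) {
  if (is.null(data) || !is.data.frame(data)) {
    stop("`data` must be a data frame.", call. = FALSE)
  }
  format <- format %||% format_from_path(path)
  if (format %in% c("sav", "dta")) {
    for (col in intersect(names(data), names(sg_variable_labels))) {
      attr(data[[col]], "label") <- unname(sg_variable_labels[col])
    }
  }
  switch(format,
    csv = readr::write_csv(data, path, na = "NA"),
    tsv = readr::write_tsv(data, path, na = "NA"),
    sav = haven::write_sav(data, path),
    dta = haven::write_dta(data, path),
    stop("Unsupported write format: ", format,
         "; use .csv, .tsv, .sav or .dta.", call. = FALSE)
  )
  invisible(path)
}

#' Export a bysg dataset
#'
#' Writes a [create_bysg()] dataset to `.csv`, `.tsv`, `.sav` (SPSS) or
#' `.dta` (Stata), chosen by file extension. CSV/TSV use comma/tab, UTF-8,
#' `.` decimal and literal `NA` for missing; SPSS/Stata exports embed
#' variable labels where defined.
#'
#' @param bysg Dataset from [create_bysg()].
#' @param path Output path; the extension selects the format.
#' @param format Optional format override.
#'
#' @return The path, invisibly.
#' @export
write_bysg <- function(bysg, path, format = NULL) {
  if (!"id_sg" %in% names(bysg)) {
    stop("`bysg` does not look like a create_bysg() dataset.", call. = FALSE)
  }
  write_sg_data(bysg, path, format)
}

#' Export a byperson dataset
#'
#' @param byperson Dataset from [create_byperson()].
#' @inheritParams write_bysg
#'
#' @return The path, invisibly.
#' @export
write_byperson <- function(byperson, path, format = NULL) {
  if (!"sg_crit123" %in% names(byperson)) {
    stop("`byperson` does not look like a create_byperson() dataset.",
         call. = FALSE)
  }
  write_sg_data(byperson, path, format)
}
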