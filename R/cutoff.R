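#' Standard error of measurement
#'
#' `S_E = sd_baseline * sqrt(1 - reliability)`. The reliability slot accepts
#' either a test-retest coefficient together with the standard deviation of
#' a normal/control population, or an internal-consistency coefficient
#' together with the clinical sample's baseline standard deviation; the two
#' conventions are numerically identical once the inputs are chosen.
#'
#' @param sd_baseline Positive standard deviation in score units.
#' @param reliability Reliability coefficient in `[0, 1]`.
#'
#' @return A single non-negative number in score units.
#' @export
#' @examples
#' standard_error_measurement(10, 0.91) # 3
standard_error_measurement <- function(sd_baseline, reliability) {
  if (!is.numeric(sd_baseline) || length(sd_baseline) != 1L ||
      is.na(sd_baseline) || sd_baseline <= 0) {
    stop("`sd_baseline` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(reliability) || length(reliability) != 1L ||
      is.na(reliability) || reliability < 0 || reliability > 1) {
    stop("`reliability` must be a single number between 0 and 1.",
         call. = FALSE)
  }
  sd_baseline * sqrt(1 - reliability)
}

#' Derive a criterion-1 cutoff from reliability statistics
#'
#' Walks the Jacobson-Truax reliable-change chain: the standard error of
#' measurement `S_E = sd * sqrt(1 - r)`, the standard error of the
#' difference between two administrations `S_diff = sqrt(2 * S_E^2)`, and
#' the reliable change value `1.96 * S_diff`. Studies differ in whether
#' they adopt `S_diff` itself or the reliable change value as the
#' criterion-1 cutoff, so both are reported and `convention` selects which
#' one is recommended.
#'
#' @inheritParams standard_error_measurement
#' @param convention `"reliable_change"` (default, `1.96 * S_diff`) or
#'   `"s_diff"`.
#' @param which_sd Documentation label recording which standard deviation
#'   was supplied: `"normal_population"` (with test-retest reliability) or
#'   `"clinical_baseline"` (with internal consistency). Does not affect the
#'   numbers.
#'
#' @return A one-row tibble with columns `sd_baseline`, `reliability`,
#'   `which_sd`, `standard_error_measurement`, `standard_error_difference`,
#'   `reliable_change_value`, `convention`, and `suggested_cutoff`.
#' @export
#' @examples
#' define_crit1_cutoff(10, 0.91)                       # suggests ~8.32
#' define_crit1_cutoff(10, 0.91, convention = "s_diff") # suggests ~4.24
define_crit1_cutoff <- function(sd_baseline, reliability,
                                convention = c("reliable_change", "s_diff"),
                                which_sd = c("normal_population",
                                             "clinical_baseline")) {
  convention <- match.arg(convention)
  which_sd <- match.arg(which_sd)
  s_e <- standard_error_measurement(sd_baseline, reliability)
  s_diff <- sqrt(2 * s_e^2)
  reliable_change <- 1.96 * s_diff
  tibble::tibble(
    sd_baseline = sd_baseline,
    reliability = reliability,
    which_sd = which_sd,
    standard_error_measurement = s_e,
    standard_error_difference = s_diff,
    reliable_change_value = reliable_change,
    convention = convention,
    suggested_cutoff = if (convention == "reliable_change") {
      reliable_change
    } else {
      s_diff
    }
  )
}
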