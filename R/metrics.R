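#' Reporting Rate: completeness of report submission
#'
#' The Reporting Rate (RR) measures submission completeness only — whether the
#' expected monthly programmatic-area reports were submitted — not the content
#' of those reports. It is computed as
#' `100 * actual / expected`, unrounded. Values above 100% can and do occur in
#' dirty data (more submissions recorded than expected reports) and are
#' deliberately not clipped: downstream diagnosis depends on seeing them.
#'
#' @param actual Number of reports actually submitted (non-negative).
#' @param expected Number of reports expected (positive; 12 per area-year for
#'   monthly reporting).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' compute_rr(actual = 12, expected = 12) # 100
#' compute_rr(actual = 13, expected = 12) # 108.33..., an erroneous excess
compute_rr <- function(actual, expected) {
  check_counts(actual, "actual")
  check_counts(expected, "expected")
  if (any(expected == 0)) {
    domain_error("Reporting Rate is undefined when `expected` is 0.")
  }
  100 * actual / expected
}

#' Reporting Rate on Time: timeliness of report submission
#'
#' The Reporting Rate on Time (RRT) is the share of expected reports submitted
#' by the monthly deadline: `100 * on_time / expected`, unrounded. As with
#' [compute_rr()], values above 100% are retained for diagnosis.
#'
#' @param on_time Number of reports submitted on time (non-negative).
#' @param expected Number of reports expected (positive).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' compute_rrt(on_time = 6, expected = 12) # 50
compute_rrt <- function(on_time, expected) {
  check_counts(on_time, "on_time")
  check_counts(expected, "expected")
  if (any(expected == 0)) {
    domain_error("Reporting Rate on Time is undefined when `expected` is 0.")
  }
  100 * on_time / expected
}

#' Cumulative Percent Completion of an annual area report
#'
#' RR and RRT say nothing about report content. Cumulative Percent Completion
#' (CPC) fills that gap: the percentage of an area's indicators that carry a
#' non-blank value in the annual report. A facility reporting 10 of PMTCT's 40
#' indicators scores 25%. An explicit zero counts as reported — the
#' blank-vs-zero ambiguity is a rendering artifact of the source system, where
#' entered zeros surface as blanks.
#'
#' @param values Vector of indicator values for one annual area report; `NA`
#'   (or `""` for character input) marks a blank cell.
#' @param n_indicators Total number of indicators defined for the area;
#'   `length(values)` must equal it.
#' @return A percentage in `[0, 100]`, unrounded.
#' @export
#' @examples
#' compute_cpc(c(3, 0, NA), n_indicators = 3) # 66.7: the zero is non-blank
compute_cpc <- function(values, n_indicators) {
  if (length(values) != n_indicators) {
    format_error(
      "Indicator vector has %d values but the area defines %d indicators.",
      length(values), n_indicators
    )
  }
  blank <- is.na(values)
  if (is.character(values)) blank <- blank | !nzchar(trimws(values))
  100 * sum(!blank) / n_indicators
}

#' Facility-year averages of CPC, RR and RRT
#'
#' The per-record averages over the six programmatic areas used to flag
#' facility-years that did not report at all: a record whose average CPC, RR
#' and RRT are all zero carries no data in any area. Missing area values
#' (one-sided merges) are treated as zero, so a facility absent from one
#' extract still averages to zero across the board.
#'
#' @param records A facility-year record table as produced by
#'   [merge_sources()].
#' @return `records` with columns `avg_cpc`, `avg_rr`, `avg_rrt` added or
#'   recomputed.
#' @export
facility_year_averages <- function(records) {
  vars <- c("cpc", "rr", "rrt")
  for (v in vars) {
    cols <- paste0(v, "_", area_codes())
    missing_cols <- setdiff(cols, names(records))
    if (length(missing_cols) > 0) {
      format_error(
        "Record table lacks area columns: %s.",
        paste(missing_cols, collapse = ", ")
      )
    }
    m <- as.matrix(records[cols])
    m[is.na(m)] <- 0
    records[[paste0("avg_", v)]] <- rowMeans(m)
  }
  records
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    domain_error("`%s` must be non-negative and non-missing.", name)
  }
  invisible(x)
}
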