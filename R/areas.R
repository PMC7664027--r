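#' Programmatic areas of the comprehensive HIV facility reporting form
#'
#' The six HIV programmatic areas reported monthly by Kenyan health facilities
#' on form MOH 731, each an independent report with a fixed indicator set:
#' HIV Counselling and Testing (HCT, 14 indicators), Prevention of
#' Mother-to-Child Transmission (PMTCT, 40), Care and Treatment (CrT, 65),
#' Voluntary Medical Male Circumcision (VMMC, 13), Post-Exposure Prophylaxis
#' (PEP, 14) and Blood Safety (BS, 3). Twelve monthly reports are expected per
#' area per year.
#'
#' @param expected_reports_per_year Expected number of monthly reports per
#'   area-year. Default 12 (one report per calendar month).
#' @return A tibble with columns `code`, `n_indicators` and
#'   `expected_reports_per_year`, one row per programmatic area, in the
#'   canonical order HCT, PMTCT, CrT, VMMC, PEP, BS.
#' @export
#' @examples
#' programmatic_areas()
programmatic_areas <- function(expected_reports_per_year = 12L) {
  if (!is.numeric(expected_reports_per_year) ||
      length(expected_reports_per_year) != 1L ||
      expected_reports_per_year < 1) {
    config_error("expected_reports_per_year", "must be a single integer >= 1")
  }
  tibble::tibble(
    code = area_codes(),
    n_indicators = c(14L, 40L, 65L, 13L, 14L, 3L),
    expected_reports_per_year = as.integer(expected_reports_per_year)
  )
}

#' Canonical programmatic-area codes
#'
#' @return Character vector of the six area codes in canonical order.
#' @export
area_codes <- function() {
  c("HCT", "PMTCT", "CrT", "VMMC", "PEP", "BS")
}

# Maximum indicator count across areas; fixes the width of the indicator file.
max_indicators <- function() 65L

indicator_col_names <- function(n = max_indicators()) {
  sprintf("ind_%03d", seq_len(n))
}
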