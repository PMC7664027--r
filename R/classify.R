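#' Situation taxonomy over (CPC, RR, RRT) triples
#'
#' Reference table of the diagnosis taxonomy: labels A-H cover the patterns of
#' zero / positive / above-100% values of Cumulative Percent Completion,
#' Reporting Rate and Reporting Rate on Time observed in annual facility
#' records, plus `ERR_X` for logically impossible combinations the base
#' taxonomy does not enumerate (timeliness exceeding submission). Situations
#' A-F and ERR_X are excluded from a clean dataset; G (complete, timely) and
#' H (complete, late) are retained.
#'
#' @return A tibble with columns `label`, `action` and `description`.
#' @export
#' @examples
#' situation_table()
situation_table <- function() {
  tibble::tibble(
    label = c("A", "B", "C", "D", "E", "F", "G", "H", "ERR_X"),
    action = c(rep("exclude", 6L), "include", "include", "exclude"),
    description = c(
      "Nothing reported: no indicator data, no submissions",
      "Empty reports submitted, some on time",
      "Empty reports submitted, none on time",
      "Indicator data present but no submission rates recorded",
      "Reporting rate above 100%: erroneous record",
      "Reporting rate and timeliness both above 100%: erroneous record",
      "Reports submitted on time with indicators included: ideal",
      "Reports with indicator data but not submitted on time",
      "Timeliness inconsistent with submissions (RRT > RR or RRT > 100)"
    )
  )
}

#' Classify a (CPC, RR, RRT) triple into a situation
#'
#' The diagnosis step of the cleaning pipeline: a total, order-independent
#' function from one area-year report's triple to its situation label.
#' Branches are evaluated in a fixed precedence: above-100% reporting rates
#' dominate (F when both RR and RRT exceed 100, otherwise E), then internally
#' inconsistent timeliness (`RRT > 100` or `RRT > RR`) is flagged `ERR_X`,
#' and the remaining space partitions into A-D and G-H by which components
#' are zero. Vectorized over the three arguments.
#'
#' @param cpc,rr,rrt Numeric vectors of percentages (non-negative; RR and RRT
#'   may exceed 100 in dirty data).
#' @return Character vector of situation labels
#'   (`A`-`H` or `ERR_X`).
#' @export
#' @examples
#' classify_situation(0, 0, 0)        # "A": nothing reported
#' classify_situation(50, 83.3, 0)    # "H": reported, but late
#' classify_situation(25, 108.3, 120) # "F": impossible rates
classify_situation <- function(cpc, rr, rrt) {
  n <- max(length(cpc), length(rr), length(rrt))
  cpc <- rep_len(as.numeric(cpc), n)
  rr <- rep_len(as.numeric(rr), n)
  rrt <- rep_len(as.numeric(rrt), n)
  if (anyNA(cpc) || anyNA(rr) || anyNA(rrt)) {
    domain_error("Triple components must be non-missing; coerce missing to 0 first.")
  }
  if (any(cpc < 0) || any(rr < 0) || any(rrt < 0)) {
    domain_error("Triple components must be non-negative percentages.")
  }
  out <- character(n)
  f <- rr > 100 & rrt > 100
  e <- !f & rr > 100
  errx <- !f & !e & (rrt > 100 | rrt > rr)
  rest <- !(f | e | errx)
  out[f] <- "F"
  out[e] <- "E"
  out[errx] <- "ERR_X"
  zc <- cpc == 0
  zr <- rr == 0
  zt <- rrt == 0
  out[rest & zc & zr & zt] <- "A"
  out[rest & zc & !zr & !zt] <- "B"
  out[rest & zc & !zr & zt] <- "C"
  out[rest & !zc & zr & zt] <- "D"
  out[rest & !zc & !zr & !zt] <- "G"
  out[rest & !zc & !zr & zt] <- "H"
  # rest & zr & !zt is impossible: rrt > rr was already routed to ERR_X
  out
}

#' Action (exclude/include) for a situation label
#'
#' @param label Character vector of situation labels.
#' @return Character vector, `"exclude"` or `"include"`.
#' @export
situation_action <- function(label) {
  tab <- situation_table()
  bad <- setdiff(unique(label), tab$label)
  if (length(bad) > 0) {
    domain_error("Unknown situation label(s): %s.", paste(bad, collapse = ", "))
  }
  tab$action[match(label, tab$label)]
}

#' Detect duplicated facility-year records
#'
#' Groups records sharing the same normalized facility name, county and year.
#' Groups whose members carry identical RR and RRT values in every area are
#' scenario-2 duplicates (same export row repeated; one copy is kept at
#' treatment). Groups with any differing RR or RRT value are scenario-1
#' duplicates (conflicting data for the same facility-year; all copies are
#' removed, since neither can be trusted). Values are compared exactly as
#' parsed — duplicates originate from the same export, so no numeric
#' tolerance is applied.
#'
#' @param records Facility-year record table from [merge_sources()].
#' @return A tibble with one row per duplicate group: `facility_key`, `year`,
#'   `n_rows` and `scenario` (`"scenario1"` or `"scenario2"`). Empty when no
#'   duplicates exist.
#' @export
detect_duplicates <- function(records) {
  rate_cols <- c(
    paste0("rr_", area_codes()),
    paste0("rrt_", area_codes())
  )
  rate_cols <- intersect(rate_cols, names(records))
  grp <- records |>
    dplyr::group_by(.data$facility_key, .data$year) |>
    dplyr::filter(dplyr::n() >= 2L)
  if (nrow(grp) == 0) {
    return(tibble::tibble(
      facility_key = character(), year = integer(),
      n_rows = integer(), scenario = character()
    ))
  }
  grp |>
    dplyr::summarise(
      n_rows = dplyr::n(),
      scenario = if (all_rows_identical(dplyr::pick(dplyr::all_of(rate_cols)))) {
        "scenario2"
      } else {
        "scenario1"
      },
      .groups = "drop"
    )
}

all_rows_identical <- function(df) {
  nrow(unique(df)) == 1L
}

#' Frequency screen for per-area excess annual reports
#'
#' A facility can have at most one annual report per programmatic area per
#' calendar year, so within a span of `year_span` years any facility with more
#' than `year_span` records for one area must contain duplicates. Flags those
#' facilities per area.
#'
#' @param area_records A long table with columns `facility_key` and
#'   `area_code` (one row per annual area report).
#' @param year_span Length of the study window in years (8 for a 2011-2018
#'   extraction); the screen threshold, parameterized rather than hard-coded.
#' @return Tibble of flagged `facility_key`, `area_code` and `n_records`.
#' @export
frequency_screen <- function(area_records, year_span) {
  if (!is.numeric(year_span) || length(year_span) != 1L || year_span < 1) {
    config_error("year_span", "must be a single positive integer")
  }
  area_records |>
    dplyr::count(.data$facility_key, .data$area_code, name = "n_records") |>
    dplyr::filter(.data$n_records > year_span)
}

#' Flag out-of-range reporting rates
#'
#' Screens every (record, area) cell for a Reporting Rate or Reporting Rate on
#' Time strictly above 100%, which is not logically possible (a facility
#' cannot submit more than the expected reports). Exactly 100% is in range.
#'
#' @param records Facility-year record table.
#' @return A long tibble with columns `facility_key`, `year`, `area_code`,
#'   `rr`, `rrt` and logical `flagged`.
#' @export
screen_out_of_range <- function(records) {
  long <- records_to_long(records)
  long$flagged <- long$rr > 100 | long$rrt > 100
  long[c("facility_key", "year", "area_code", "rr", "rrt", "flagged")]
}

# Wide record table -> long (facility_key, year, area_code, cpc, rr, rrt),
# with missing components coerced to 0 (the classification-side view; the wide
# table keeps the raw NA distinction for audit).
records_to_long <- function(records) {
  records$.row_id <- seq_len(nrow(records))
  long <- tidyr::pivot_longer(
    records[c(".row_id", "facility_key", "year",
              paste0("cpc_", area_codes()),
              paste0("rr_", area_codes()),
              paste0("rrt_", area_codes()))],
    cols = -c(".row_id", "facility_key", "year"),
    names_to = c(".value", "area_code"),
    names_pattern = "^(cpc|rr|rrt)_(.+)$"
  )
  long$area_code <- factor(long$area_code, levels = area_codes())
  long$cpc[is.na(long$cpc)] <- 0
  long$rr[is.na(long$rr)] <- 0
  long$rrt[is.na(long$rrt)] <- 0
  long$area_code <- as.character(long$area_code)
  long
}
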