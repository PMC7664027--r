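#' Remove facility-years that did not report at all
#'
#' A facility-year whose average Cumulative Percent Completion, Reporting Rate
#' and Reporting Rate on Time are all zero across the six programmatic areas
#' carries no data and is identified as not having reported for that year;
#' such records are excluded up front.
#'
#' @param records Facility-year record table with `avg_*` columns.
#' @param cycle_id Cycle number for the accounting report.
#' @return List with `kept` (records), `report` (one-row cycle tibble) and
#'   `audit` (one row per removed record with the reason).
#' @export
drop_nonreporting_facility_years <- function(records, cycle_id = 1L) {
  drop <- records$avg_cpc == 0 & records$avg_rr == 0 & records$avg_rrt == 0
  cycle_result(records, drop, cycle_id, "nonreporting_facility_year",
               "average CPC, RR and RRT all zero across areas")
}

#' Remove facility-years with erroneous reporting rates
#'
#' Excludes every facility-year record containing, in any area, a Reporting
#' Rate above 100%, a Reporting Rate on Time above 100%, or a timeliness rate
#' exceeding the submission rate — all logically impossible, since on-time
#' reports are a subset of submitted reports and neither can exceed the
#' expected count.
#'
#' @inheritParams drop_nonreporting_facility_years
#' @return Same structure as [drop_nonreporting_facility_years()].
#' @export
drop_erroneous <- function(records, cycle_id = 2L) {
  long <- records_to_long(records)
  bad_rows <- long$.row_id[long$rr > 100 | long$rrt > 100 | long$rrt > long$rr]
  drop <- seq_len(nrow(records)) %in% bad_rows
  cycle_result(records, drop, cycle_id, "erroneous_rates",
               "RR > 100%, RRT > 100% or RRT > RR in at least one area")
}

#' Treat duplicated facility-year records
#'
#' Applies the duplicate treatment rules: for scenario-1 groups (same
#' facility, county and year but conflicting RR/RRT data) every member is
#' removed, since none can be trusted; for scenario-2 groups (identical data)
#' all but one member is removed, keeping the first in a stable sort by
#' record key.
#'
#' @param records Facility-year record table.
#' @param groups Duplicate groups from [detect_duplicates()]; detected from
#'   `records` when omitted.
#' @param cycle_id Cycle number for the accounting report.
#' @return Same structure as [drop_nonreporting_facility_years()], with
#'   per-scenario removal counts attached as attributes `n_scenario1` /
#'   `n_scenario2` on the report.
#' @export
treat_duplicates <- function(records, groups = detect_duplicates(records),
                             cycle_id = 3L) {
  drop <- rep(FALSE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  n_s1 <- 0L
  n_s2 <- 0L
  if (nrow(groups) > 0) {
    grp_key <- paste(records$facility_key, records$year, sep = "\r")
    occ <- if ("occ" %in% names(records)) records[["occ"]] else seq_len(nrow(records))
    ord <- order(records$facility_key, records$year, occ)
    for (g in seq_len(nrow(groups))) {
      members <- which(grp_key == paste(groups$facility_key[g], groups$year[g], sep = "\r"))
      members <- members[order(match(members, ord))]
      if (groups$scenario[g] == "scenario1") {
        drop[members] <- TRUE
        reason[members] <- "scenario-1 duplicate: conflicting RR/RRT, all copies removed"
        n_s1 <- n_s1 + length(members)
      } else {
        rm_members <- members[-1L]
        drop[rm_members] <- TRUE
        reason[rm_members] <- "scenario-2 duplicate: identical copy removed, one kept"
        n_s2 <- n_s2 + length(rm_members)
      }
    }
  }
  out <- cycle_result(records, drop, cycle_id, "duplicates", reason)
  attr(out$report, "n_scenario1") <- n_s1
  attr(out$report, "n_scenario2") <- n_s2
  out
}

#' Disaggregate facility-year records into six per-area datasets
#'
#' Fans each facility-year record out into one row per programmatic area,
#' carrying the single-area (CPC, RR, RRT) triple, the facility metadata and
#' EMR status, and the situation label assigned by [classify_situation()].
#' Facilities offer different services, so downstream treatment and analysis
#' operate per area.
#'
#' @param records Facility-year record table.
#' @return Named list of six tibbles, one per area code, each with
#'   `nrow(records)` rows.
#' @export
disaggregate_by_area <- function(records) {
  long <- records_to_long(records)
  long$situation <- classify_situation(long$cpc, long$rr, long$rrt)
  meta_cols <- intersect(
    c("facility_name", "county", "occ", "level", "facility_type", "ownership", "has_emr"),
    names(records)
  )
  meta <- records[c("facility_key", "year", meta_cols)]
  meta$.row_id <- seq_len(nrow(records))
  long <- dplyr::left_join(
    long, meta,
    by = c(".row_id", "facility_key", "year")
  )
  cols <- c("facility_key", "facility_name", "county", "year", "area_code",
            "cpc", "rr", "rrt", "situation", meta_cols[!meta_cols %in%
            c("facility_name", "county")])
  long <- long[intersect(cols, names(long))]
  split(long, factor(long$area_code, levels = area_codes()))
}

#' Retain only ideal and late-but-complete reports in one area dataset
#'
#' The per-area treatment step: rows in situations A-F (and the inconsistent
#' extension ERR_X) are removed; only situations G (reported on time with
#' indicator data) and H (reported with data, but late) enter the final clean
#' dataset. Per-situation counts are returned for the distribution analysis.
#'
#' @param area_dataset One element of [disaggregate_by_area()].
#' @param cycle_id Cycle number for the accounting report.
#' @return List with `kept`, `report`, `audit` and `counts` (named integer
#'   vector of row counts per situation label present before treatment).
#' @export
apply_situation_treatment <- function(area_dataset, cycle_id = 4L) {
  counts <- table(factor(area_dataset$situation, levels = situation_table()$label))
  keep <- situation_action(area_dataset$situation) == "include"
  area_label <- if (nrow(area_dataset) > 0) area_dataset$area_code[1] else "empty"
  res <- cycle_result(
    area_dataset, !keep, cycle_id,
    paste0("situation_treatment_", area_label),
    sprintf("situation %s excluded", area_dataset$situation)
  )
  res$counts <- stats::setNames(as.integer(counts), names(counts))
  res
}

#' Run the full iterative cleaning pipeline
#'
#' Executes the treatment phase as ordered cleaning cycles, each producing a
#' new dataset and an accounting row: (1) facility-years with no data
#' removed, (2) facility-years with impossible reporting rates removed,
#' (3) duplicates treated (conflicting copies all removed, identical copies
#' deduplicated), then the surviving records are disaggregated into six
#' per-area datasets and (4) per-area situation treatment retains only
#' situations G and H. Every removal is logged with its record key, cycle,
#' rule and reason. The record set entering the duplicate cycle is kept as
#' `dataset4`, the denominator of the situation-distribution analysis.
#'
#' @param records Facility-year record table from [merge_sources()].
#' @param order Character vector ordering the record-level cycles; any
#'   permutation of `c("nonreporting", "erroneous", "duplicates")`.
#' @return List with `area_datasets` (six clean tibbles), `records_clean`
#'   (facility-year records surviving the record-level cycles), `cycles`
#'   (accounting tibble, one row per cycle), `audit` (one row per removed
#'   record), `dataset4` (records entering duplicate treatment), `dataset4_n`,
#'   `situation_counts` (area x situation matrix of pre-treatment counts on
#'   the post-duplicate data), `dup_removed` (duplicate records removed) and
#'   `pre_treatment_areas` (the six disaggregated datasets before situation
#'   treatment).
#' @export
run_cleaning_cycles <- function(records,
                                order = c("nonreporting", "erroneous", "duplicates")) {
  if (!setequal(order, c("nonreporting", "erroneous", "duplicates"))) {
    config_error("order", "must be a permutation of nonreporting, erroneous, duplicates")
  }
  cycles <- list()
  audits <- list()
  current <- records
  dataset4 <- NULL
  dup_removed <- 0L
  cycle_id <- 0L
  for (stage in order) {
    cycle_id <- cycle_id + 1L
    if (stage == "duplicates") dataset4 <- current
    res <- switch(stage,
      nonreporting = drop_nonreporting_facility_years(current, cycle_id),
      erroneous = drop_erroneous(current, cycle_id),
      duplicates = treat_duplicates(current, cycle_id = cycle_id)
    )
    if (stage == "duplicates") dup_removed <- res$report$n_removed
    cycles[[length(cycles) + 1L]] <- res$report
    audits[[length(audits) + 1L]] <- res$audit
    current <- res$kept
  }
  if (is.null(dataset4)) dataset4 <- current

  area_sets <- disaggregate_by_area(current)
  situation_counts <- matrix(
    0L, nrow = length(area_sets), ncol = nrow(situation_table()),
    dimnames = list(names(area_sets), situation_table()$label)
  )
  clean_sets <- list()
  for (a in names(area_sets)) {
    cycle_id <- cycle_id + 1L
    res <- apply_situation_treatment(area_sets[[a]], cycle_id)
    situation_counts[a, names(res$counts)] <- res$counts
    cycles[[length(cycles) + 1L]] <- res$report
    audits[[length(audits) + 1L]] <- res$audit
    clean_sets[[a]] <- res$kept
  }
  list(
    area_datasets = clean_sets,
    records_clean = current,
    cycles = dplyr::bind_rows(cycles),
    audit = dplyr::bind_rows(audits),
    dataset4 = dataset4,
    dataset4_n = nrow(dataset4),
    situation_counts = situation_counts,
    dup_removed = dup_removed,
    pre_treatment_areas = area_sets
  )
}

# Shared accounting for one cleaning cycle: n_in = n_removed + n_out always.
cycle_result <- function(data, drop, cycle_id, rule, reason) {
  drop[is.na(drop)] <- FALSE
  n_in <- nrow(data)
  n_removed <- sum(drop)
  report <- tibble::tibble(
    cycle_id = as.integer(cycle_id),
    rule = rule,
    n_in = n_in,
    n_removed = n_removed,
    n_out = n_in - n_removed
  )
  removed <- data[drop, , drop = FALSE]
  reason_vec <- if (length(reason) == 1L) rep(reason, n_in) else reason
  audit <- tibble::tibble(
    facility_key = removed[["facility_key"]],
    year = removed[["year"]],
    area_code = if ("area_code" %in% names(removed)) {
      removed[["area_code"]]
    } else {
      rep(NA_character_, nrow(removed))
    },
    cycle_id = as.integer(cycle_id),
    rule = rule,
    reason = reason_vec[drop]
  )
  list(kept = data[!drop, , drop = FALSE], report = report, audit = audit)
}
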