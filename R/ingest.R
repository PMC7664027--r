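#' Read a reporting-rate extract
#'
#' Reads the per-facility, per-year, per-programmatic-area reporting extract:
#' expected, submitted and on-time report counts plus the percentage Reporting
#' Rate and Reporting Rate on Time. Percentages are parsed as plain numbers —
#' values above 100% are retained, not clipped, because the diagnosis stage
#' depends on seeing them. Missing cells stay missing.
#'
#' @param path Path to `reporting_extract.csv`.
#' @return Tibble with one row per (facility, county, year, area).
#' @export
read_reporting_extract <- function(path) {
  required <- c(
    "facility_name", "county", "year", "area_code", "expected_reports",
    "actual_reports", "actual_on_time", "reporting_rate_pct",
    "reporting_rate_on_time_pct"
  )
  df <- read_source_csv(path, required, extra_ok = FALSE)
  for (col in c("expected_reports", "actual_reports", "actual_on_time",
                "reporting_rate_pct", "reporting_rate_on_time_pct", "year")) {
    df[[col]] <- parse_numeric_col(df[[col]], col, path)
  }
  df$year <- as.integer(df$year)
  df
}

#' Read an annual indicator extract
#'
#' Reads the per-facility, per-year, per-area annual HIV-indicator extract.
#' The file is rectangular with `ind_001` up to the maximum indicator count of
#' any area; a row for an area with fewer indicators must leave the trailing
#' columns empty. Within an area's indicator columns, a blank cell and an
#' explicit "0" are distinct states: blank means no value was rendered, zero
#' means a reported count of zero.
#'
#' @param path Path to `indicator_extract.csv`.
#' @param areas Programmatic-area table, see [programmatic_areas()].
#' @return Tibble with identity columns and `ind_001`... columns (`NA` =
#'   blank), plus `n_nonblank` counted over each row's area-specific columns.
#' @export
read_indicator_extract <- function(path, areas = programmatic_areas()) {
  n_max <- max(areas$n_indicators)
  required <- c("facility_name", "county", "year", "area_code",
                indicator_col_names(n_max))
  df <- read_source_csv(path, required, extra_ok = FALSE)
  df$year <- as.integer(parse_numeric_col(df$year, "year", path))
  bad_area <- setdiff(unique(df$area_code), areas$code)
  if (length(bad_area) > 0) {
    format_error(
      "`%s` contains unknown programmatic area(s): %s.",
      path, paste(bad_area, collapse = ", ")
    )
  }
  ind_cols <- indicator_col_names(n_max)
  for (col in ind_cols) {
    x <- df[[col]]
    if (is.character(x)) x[!nzchar(trimws(x))] <- NA
    df[[col]] <- parse_numeric_col(x, col, path)
  }
  n_ind <- areas$n_indicators[match(df$area_code, areas$code)]
  ind_mat <- as.matrix(df[ind_cols])
  # values beyond an area's indicator set are a column-count violation
  col_idx <- matrix(rep(seq_len(n_max), each = nrow(df)), nrow = nrow(df))
  overflow <- !is.na(ind_mat) & col_idx > n_ind
  if (any(overflow)) {
    bad <- which(rowSums(overflow) > 0)[1L]
    format_error(
      "`%s` row %d: area %s defines %d indicators but values are present beyond column ind_%03d.",
      path, bad, df$area_code[bad], n_ind[bad], n_ind[bad]
    )
  }
  df$n_nonblank <- rowSums(!is.na(ind_mat) & col_idx <= n_ind)
  df$n_indicators <- n_ind
  df
}

#' Read the facility master list and the EMR-status list
#'
#' Builds the facility registry: level (II-VI), facility type and ownership
#' from the master list, with `has_emr` set true for facilities present on the
#' EMR list and false otherwise. Facilities are keyed by normalized
#' (name, county); a duplicated key in the master list is a format error.
#'
#' @param facility_path Path to `facility_list.csv`.
#' @param emr_path Path to `emr_list.csv`.
#' @return Registry tibble with `facility_key`, identity and metadata columns
#'   and logical `has_emr`.
#' @export
read_facility_list <- function(facility_path, emr_path) {
  fac <- read_source_csv(
    facility_path,
    c("facility_name", "county", "level", "facility_type", "ownership"),
    extra_ok = FALSE
  )
  fac$facility_key <- facility_key(fac$facility_name, fac$county)
  dup <- fac$facility_key[duplicated(fac$facility_key)]
  if (length(dup) > 0) {
    format_error(
      "`%s` has duplicated (facility, county) entries: %s.",
      facility_path, paste(unique(dup), collapse = "; ")
    )
  }
  emr <- read_source_csv(emr_path, c("facility_name", "county"), extra_ok = FALSE)
  emr_keys <- unique(facility_key(emr$facility_name, emr$county))
  fac$has_emr <- fac$facility_key %in% emr_keys
  fac
}

#' Merge the source datasets into facility-year records
#'
#' Builds the evaluation dataset: one facility-year record per (normalized
#' facility name + county, year) occurrence, holding the (CPC, RR, RRT)
#' triple for each of the six programmatic areas, the three per-record
#' averages and the joined facility metadata. CPC is computed from the
#' indicator extract; an area present in only one extract keeps the other
#' components as missing (`NA`) in the record for audit — classification and
#' averaging coerce them to zero downstream. Duplicated source rows pass
#' through unmerged (multiplicity preserved, paired by occurrence within
#' their key) so the duplicate detector sees them. Facilities absent from the
#' registry get metadata `"unknown"`. Every partial match is logged.
#'
#' @param reporting Output of [read_reporting_extract()].
#' @param indicators Output of [read_indicator_extract()].
#' @param registry Output of [read_facility_list()], or `NULL` to skip the
#'   metadata join.
#' @param areas Programmatic-area table.
#' @return List with `records` (wide facility-year tibble) and `log` (tibble
#'   of `facility`, `year`, `issue`).
#' @export
merge_sources <- function(reporting, indicators, registry = NULL,
                          areas = programmatic_areas()) {
  rep_l <- tibble::tibble(
    facility_key = facility_key(reporting$facility_name, reporting$county),
    facility_name = reporting$facility_name,
    county = reporting$county,
    year = reporting$year,
    area_code = reporting$area_code,
    expected_reports = reporting$expected_reports,
    actual_reports = reporting$actual_reports,
    actual_on_time = reporting$actual_on_time,
    rr = reporting$reporting_rate_pct,
    rrt = reporting$reporting_rate_on_time_pct
  ) |>
    dplyr::group_by(.data$facility_key, .data$year, .data$area_code) |>
    dplyr::mutate(occ = dplyr::row_number()) |>
    dplyr::ungroup()

  ind_l <- tibble::tibble(
    facility_key = facility_key(indicators$facility_name, indicators$county),
    facility_name = indicators$facility_name,
    county = indicators$county,
    year = indicators$year,
    area_code = indicators$area_code,
    cpc = 100 * indicators$n_nonblank / indicators$n_indicators
  ) |>
    dplyr::group_by(.data$facility_key, .data$year, .data$area_code) |>
    dplyr::mutate(occ = dplyr::row_number()) |>
    dplyr::ungroup()

  joined <- dplyr::full_join(
    rep_l, ind_l,
    by = c("facility_key", "year", "area_code", "occ"),
    suffix = c("", ".ind")
  )
  joined$facility_name <- dplyr::coalesce(joined$facility_name, joined$facility_name.ind)
  joined$county <- dplyr::coalesce(joined$county, joined$county.ind)

  log <- dplyr::bind_rows(
    joined |>
      dplyr::filter(is.na(.data$rr) & is.na(.data$rrt)) |>
      dplyr::transmute(
        facility = .data$facility_name, year = .data$year,
        issue = sprintf("area %s: indicator data without a reporting row", .data$area_code)
      ),
    joined |>
      dplyr::filter(!is.na(.data$rr) & is.na(.data$cpc)) |>
      dplyr::transmute(
        facility = .data$facility_name, year = .data$year,
        issue = sprintf("area %s: reporting row without indicator data", .data$area_code)
      )
  )

  wide <- joined |>
    dplyr::select(
      "facility_key", "facility_name", "county", "year", "occ",
      "area_code", "cpc", "rr", "rrt"
    ) |>
    tidyr::pivot_wider(
      names_from = "area_code",
      values_from = c("cpc", "rr", "rrt"),
      names_glue = "{.value}_{area_code}"
    )
  # areas absent from both extracts for some records: ensure all 18 columns
  for (v in c("cpc", "rr", "rrt")) {
    for (a in areas$code) {
      col <- paste0(v, "_", a)
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
  }
  wide <- facility_year_averages(wide)

  if (!is.null(registry)) {
    meta <- registry[c("facility_key", "level", "facility_type", "ownership", "has_emr")]
    wide <- dplyr::left_join(wide, meta, by = "facility_key")
    unmatched <- is.na(wide$level) & is.na(wide$facility_type)
    if (any(unmatched)) {
      log <- dplyr::bind_rows(
        log,
        wide |>
          dplyr::filter(unmatched) |>
          dplyr::distinct(.data$facility_name, .data$year) |>
          dplyr::transmute(
            facility = .data$facility_name, year = .data$year,
            issue = "facility not found in master list"
          )
      )
    }
    wide$level[is.na(wide$level)] <- "unknown"
    wide$facility_type[is.na(wide$facility_type)] <- "unknown"
    wide$ownership[is.na(wide$ownership)] <- "unknown"
    wide$has_emr <- ifelse(is.na(wide$has_emr), "unknown",
                           ifelse(wide$has_emr, "true", "false"))
    registry_only <- setdiff(registry$facility_key, wide$facility_key)
    if (length(registry_only) > 0) {
      log <- dplyr::bind_rows(
        log,
        tibble::tibble(
          facility = registry$facility_name[match(registry_only, registry$facility_key)],
          year = NA_integer_,
          issue = "master-list facility absent from extracts; dropped"
        )
      )
    }
  } else {
    wide$level <- "unknown"
    wide$facility_type <- "unknown"
    wide$ownership <- "unknown"
    wide$has_emr <- "unknown"
  }

  ord <- c(
    "facility_key", "facility_name", "county", "year", "occ",
    paste0("cpc_", areas$code), paste0("rr_", areas$code),
    paste0("rrt_", areas$code),
    "avg_cpc", "avg_rr", "avg_rrt",
    "level", "facility_type", "ownership", "has_emr"
  )
  list(records = wide[ord], log = log)
}

# -- internal CSV plumbing ---------------------------------------------------

read_source_csv <- function(path, required, extra_ok = TRUE) {
  if (!file.exists(path)) io_error("File `%s` does not exist.", path)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE,
    show_col_types = FALSE
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    format_error(
      "`%s` is missing required column(s): %s.",
      path, paste(missing, collapse = ", ")
    )
  }
  if (!extra_ok) {
    extra <- setdiff(names(df), required)
    if (length(extra) > 0) {
      format_error(
        "`%s` has unexpected column(s): %s.",
        path, paste(extra, collapse = ", ")
      )
    }
  }
  df
}

parse_numeric_col <- function(x, col, path) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  x[!nzchar(x)] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    format_error(
      "`%s` column `%s`: non-numeric value \"%s\" at data row %d.",
      path, col, x[bad[1L]], bad[1L]
    )
  }
  out
}
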