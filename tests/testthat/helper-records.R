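# Builders for facility-year record tables and synthetic source directories
# used across the test files.

# One wide facility-year record row. Per-area triples are passed as named
# arguments, e.g. HCT = c(cpc, rr, rrt); unnamed areas default to `default`.
record_row <- function(facility = "Facility X", county = "County 01",
                       year = 2015L, occ = 1L, default = c(0, 0, 0), ...) {
  triples <- list(...)
  row <- tibble::tibble(
    facility_key = dhisclean:::facility_key(facility, county),
    facility_name = facility,
    county = county,
    year = as.integer(year),
    occ = as.integer(occ)
  )
  for (a in area_codes()) {
    tr <- if (a %in% names(triples)) triples[[a]] else default
    row[[paste0("cpc_", a)]] <- tr[1]
    row[[paste0("rr_", a)]] <- tr[2]
    row[[paste0("rrt_", a)]] <- tr[3]
  }
  row$level <- "II"
  row$facility_type <- "dispensary"
  row$ownership <- "MoH"
  row$has_emr <- "false"
  facility_year_averages(row)
}

record_table <- function(...) {
  dplyr::bind_rows(...)
}

# Generate, write and re-ingest a synthetic dataset; returns everything a
# round-trip test needs.
build_synthetic_case <- function(cfg, dir = tempfile("dhisclean-case-")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  registry <- generate_facility_registry(cfg)
  extracts <- generate_extracts(registry, cfg)
  extracts <- inject_duplicates(extracts, cfg)
  paths <- write_sources(registry, extracts, dir)
  reporting <- read_reporting_extract(paths[["reporting"]])
  indicators <- read_indicator_extract(paths[["indicators"]])
  reg <- read_facility_list(paths[["facilities"]], paths[["emr"]])
  merged <- merge_sources(reporting, indicators, reg)
  list(
    cfg = cfg, registry = registry, extracts = extracts, paths = paths,
    merged = merged
  )
}

truth_area_key <- function(truth) {
  paste(
    dhisclean:::facility_key(truth$facility_name, truth$county),
    truth$year, truth$area_code,
    sep = "\r"
  )
}

# Expected retained (facility-year, area) rows computed from truth labels
# alone: G/H areas of records that are not all-A, contain no injected E/F
# area, and are not scenario-1 duplicates; scenario-2 groups contribute one
# representative.
expected_retained_from_truth <- function(truth) {
  orig <- truth[!truth$is_copy, ]
  rec_key <- paste(
    dhisclean:::facility_key(orig$facility_name, orig$county),
    orig$year, sep = "\r"
  )
  by_rec <- split(orig, rec_key)
  out <- list()
  for (k in names(by_rec)) {
    rec <- by_rec[[k]]
    if (all(rec$situation == "A")) next
    if (any(rec$situation %in% c("E", "F"))) next
    if (any(rec$is_duplicate == "scenario1")) next
    gh <- rec[rec$situation %in% c("G", "H"), ]
    if (nrow(gh) > 0) {
      out[[k]] <- tibble::tibble(
        facility_key = dhisclean:::facility_key(gh$facility_name, gh$county),
        year = gh$year,
        area_code = gh$area_code,
        situation = gh$situation
      )
    }
  }
  dplyr::bind_rows(out)
}
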