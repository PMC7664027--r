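#' Configuration for the synthetic DHIS2 extract generator
#'
#' Defines the statistical conditions under which DHIS2-like source files are
#' generated: the facility population, study years, per-area situation
#' mixtures, duplicate-injection rates and the blank-zero rendering rate.
#' Defaults emulate the structure of national HIV-indicator reporting in
#' Kenya 2011-2018: six programmatic areas, 12 expected monthly reports per
#' area-year, roughly half of facility-years carrying no data at all, a
#' per-area situation mixture dominated by ideal reporting in high-volume
#' areas (HCT, PMTCT) and by non-service provision in low-volume areas
#' (VMMC, BS), rare (~0.03%) above-100% rate errors, and rare duplicates.
#'
#' @param n_facilities Number of facilities to simulate (>= 1).
#' @param years Calendar years covered, strictly increasing. Default
#'   2011-2018.
#' @param counties County label pool. Default: 47 synthetic county names.
#' @param situation_mix Named list, one element per programmatic area code,
#'   each a named probability vector over situation labels A-H summing to 1.
#'   Situation draws are independent per area within a facility-year,
#'   conditional on the facility-year not being a facility-level non-reporter.
#' @param facility_a_rate Probability that an entire facility-year is a
#'   non-reporter (situation A in all six areas simultaneously), so that
#'   facility-level all-zero records exist. Default 0.5.
#' @param dup_scenario1_rate Fraction of facility-year rows duplicated with
#'   perturbed RR/RRT data (conflicting duplicates). Default 5e-4.
#' @param dup_scenario2_rate Fraction duplicated verbatim (identical
#'   duplicates). Default 5e-4.
#' @param blank_zero_rate Probability that an entered zero indicator value is
#'   rendered as a blank cell, emulating the source system's display of zeros
#'   as blanks. Default 1.
#' @param expected_reports_per_year Expected monthly reports per area-year.
#'   Default 12.
#' @param seed Root RNG seed. Child streams are derived per (facility, year,
#'   area) by counter, so enlarging `n_facilities` does not reshuffle
#'   earlier facilities.
#' @return A validated list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_facilities = 5, seed = 1)
generator_config <- function(n_facilities,
                             years = 2011:2018,
                             counties = default_counties(),
                             situation_mix = default_situation_mix(),
                             facility_a_rate = 0.5,
                             dup_scenario1_rate = 5e-4,
                             dup_scenario2_rate = 5e-4,
                             blank_zero_rate = 1,
                             expected_reports_per_year = 12L,
                             seed = 1L) {
  if (!is.numeric(n_facilities) || length(n_facilities) != 1L ||
      is.na(n_facilities) || n_facilities < 1) {
    config_error("n_facilities", "must be a single integer >= 1")
  }
  if (length(years) == 0 || anyNA(years) || any(diff(years) <= 0)) {
    config_error("years", "must be non-empty and strictly increasing")
  }
  if (length(counties) == 0) {
    config_error("counties", "must be a non-empty character vector")
  }
  if (!setequal(names(situation_mix), area_codes())) {
    config_error("situation_mix", "must have one mixture per programmatic area code")
  }
  for (a in area_codes()) {
    mix <- situation_mix[[a]]
    if (is.null(names(mix)) || !all(names(mix) %in% LETTERS[1:8]) ||
        any(mix < 0)) {
      config_error(
        "situation_mix",
        sprintf("for area %s must be a non-negative vector named by situations A-H", a)
      )
    }
    if (abs(sum(mix) - 1) > 1e-9) {
      config_error(
        "situation_mix",
        sprintf("for area %s must sum to 1 (got %.12f)", a, sum(mix))
      )
    }
  }
  for (nm in c("facility_a_rate", "dup_scenario1_rate",
               "dup_scenario2_rate", "blank_zero_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      config_error(nm, "must be a single probability in [0, 1]")
    }
  }
  if (!is.numeric(expected_reports_per_year) || expected_reports_per_year < 1) {
    config_error("expected_reports_per_year", "must be a single integer >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    config_error("seed", "must be a single integer")
  }
  structure(
    list(
      n_facilities = as.integer(n_facilities),
      years = as.integer(years),
      counties = as.character(counties),
      situation_mix = lapply(situation_mix[area_codes()], function(m) m / sum(m)),
      facility_a_rate = facility_a_rate,
      dup_scenario1_rate = dup_scenario1_rate,
      dup_scenario2_rate = dup_scenario2_rate,
      blank_zero_rate = blank_zero_rate,
      expected_reports_per_year = as.integer(expected_reports_per_year),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Default synthetic county pool
#'
#' @return 47 synthetic county labels (one per Kenyan county, names synthetic).
#' @export
default_counties <- function() {
  sprintf("County %02d", 1:47)
}

#' Default per-area situation mixtures
#'
#' One probability vector over situations A-H per programmatic area,
#' conditional on the facility-year reporting at all. The weights reproduce
#' the broad per-area structure of cleaned national HIV reporting: HCT and
#' PMTCT dominated by ideal reporting, VMMC and BS dominated by non-service
#' provision, PEP with a large share of empty submitted reports, and rare
#' above-100% rate errors in every area.
#'
#' @return Named list of named probability vectors.
#' @export
default_situation_mix <- function() {
  w <- list(
    HCT   = c(A = 1.86,  B = 2.68,  C = 0.75, D = 0.66, E = 0.02, F = 0.01, G = 92.44, H = 1.57),
    PMTCT = c(A = 7.45,  B = 6.15,  C = 0.75, D = 1.97, E = 0.02, F = 0.01, G = 81.52, H = 2.13),
    CrT   = c(A = 52.86, B = 1.32,  C = 0.32, D = 1.66, E = 0.02, F = 0.01, G = 42.60, H = 1.20),
    VMMC  = c(A = 94.59, B = 2.81,  C = 1.13, D = 0.78, E = 0.02, F = 0.01, G = 0.63,  H = 0.03),
    PEP   = c(A = 58.36, B = 18.04, C = 0.76, D = 0.71, E = 0.02, F = 0.01, G = 21.82, H = 0.28),
    BS    = c(A = 97.53, B = 1.70,  C = 0.19, D = 0.09, E = 0.02, F = 0.01, G = 0.45,  H = 0.01)
  )
  lapply(w, function(v) v / sum(v))
}

#' Generate a synthetic facility registry
#'
#' Produces `n_facilities` facilities with unique names, a county from the
#' configured pool, a care level (II-VI), a facility type matched to the
#' level, an ownership class and an EMR flag. Deterministic given the
#' config's seed.
#'
#' @param config A [generator_config()].
#' @return Tibble with columns `facility_name`, `county`, `level`,
#'   `facility_type`, `ownership`, `has_emr`.
#' @export
generate_facility_registry <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  levels <- c("II", "III", "IV", "V", "VI")
  types <- c(
    II = "dispensary", III = "health centre", IV = "sub-county hospital",
    V = "county referral hospital", VI = "national referral hospital"
  )
  ownerships <- c("MoH", "private practice", "faith-based", "NGO")
  n <- config$n_facilities
  county <- character(n)
  level <- character(n)
  ownership <- character(n)
  has_emr <- logical(n)
  for (i in seq_len(n)) {
    with_seed(child_seed(config$seed, i, 0L, 0L), {
      county[i] <- sample(config$counties, 1L)
      level[i] <- sample(levels, 1L, prob = c(0.45, 0.3, 0.15, 0.07, 0.03))
      ownership[i] <- sample(ownerships, 1L, prob = c(0.5, 0.25, 0.15, 0.1))
      has_emr[i] <- stats::runif(1) < 0.25
    })
  }
  tibble::tibble(
    facility_name = sprintf("Facility %05d", seq_len(n)),
    county = county,
    level = level,
    facility_type = unname(types[level]),
    ownership = ownership,
    has_emr = has_emr
  )
}

#' Generate synthetic reporting and indicator extracts with truth labels
#'
#' For every facility, year and programmatic area, draws a situation from the
#' configured mixture (or situation A for all six areas when the facility-year
#' is drawn as a facility-level non-reporter) and emits a reporting-extract
#' row and an indicator-extract row whose (CPC, RR, RRT) pattern satisfies
#' that situation: empty indicator sets for A-C, indicator data with zeroed
#' submission counts for D, above-100% rates for E/F (drawn uniformly over
#' (100, 200] via excess submission counts), and in-range counts for G/H.
#' Reporting rates are emitted both as counts and as percentages, coherent
#' (`pct = 100 * count / expected`) for every row. Every emitted area record
#' gets exactly one ground-truth label.
#'
#' @param registry Output of [generate_facility_registry()].
#' @param config The same [generator_config()].
#' @return List with elements `reporting` (tibble), `indicators` (tibble with
#'   `ind_001`..`ind_065`, `NA` = blank) and `truth` (one row per area record:
#'   `facility_name`, `county`, `year`, `area_code`, `situation`,
#'   `facility_level_a`, `is_duplicate`, `is_copy`).
#' @export
generate_extracts <- function(registry, config) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(registry) != config$n_facilities) {
    config_error("registry", "does not match config$n_facilities")
  }
  areas <- programmatic_areas(config$expected_reports_per_year)
  n_fac <- config$n_facilities
  years <- config$years
  n_rows <- n_fac * length(years) * nrow(areas)
  E <- config$expected_reports_per_year

  fac_i <- integer(n_rows)
  year <- integer(n_rows)
  area <- character(n_rows)
  situation <- character(n_rows)
  fac_a <- logical(n_rows)
  actual <- integer(n_rows)
  on_time <- integer(n_rows)
  ind_mat <- matrix(NA_integer_, n_rows, max_indicators())

  r <- 0L
  for (i in seq_len(n_fac)) {
    for (yi in seq_along(years)) {
      is_fac_a <- with_seed(
        child_seed(config$seed, i, yi, 0L),
        stats::runif(1) < config$facility_a_rate
      )
      for (ai in seq_len(nrow(areas))) {
        r <- r + 1L
        a_code <- areas$code[ai]
        fac_i[r] <- i
        year[r] <- years[yi]
        area[r] <- a_code
        fac_a[r] <- is_fac_a
        with_seed(child_seed(config$seed, i, yi, ai), {
          sit <- if (is_fac_a) {
            "A"
          } else {
            mix <- config$situation_mix[[a_code]]
            sample(names(mix), 1L, prob = mix)
          }
          situation[r] <- sit
          counts <- draw_counts(sit, E)
          actual[r] <- counts[1L]
          on_time[r] <- counts[2L]
          if (sit %in% c("D", "E", "F", "G", "H")) {
            ind_mat[r, seq_len(areas$n_indicators[ai])] <-
              draw_indicators(areas$n_indicators[ai], config$blank_zero_rate)
          }
        })
      }
    }
  }

  base <- tibble::tibble(
    facility_name = registry$facility_name[fac_i],
    county = registry$county[fac_i],
    year = year,
    area_code = area
  )
  reporting <- dplyr::bind_cols(
    base,
    tibble::tibble(
      expected_reports = E,
      actual_reports = actual,
      actual_on_time = on_time,
      reporting_rate_pct = 100 * actual / E,
      reporting_rate_on_time_pct = 100 * on_time / E
    )
  )
  colnames(ind_mat) <- indicator_col_names()
  indicators <- dplyr::bind_cols(base, tibble::as_tibble(ind_mat))
  truth <- dplyr::bind_cols(
    base,
    tibble::tibble(
      situation = situation,
      facility_level_a = fac_a,
      is_duplicate = "none",
      is_copy = FALSE
    )
  )
  list(reporting = reporting, indicators = indicators, truth = truth)
}

# Submission counts satisfying a situation's (RR, RRT) pattern.
draw_counts <- function(situation, E) {
  switch(situation,
    A = ,
    D = c(0L, 0L),
    B = {
      a <- sample.int(E, 1L)
      c(a, sample.int(a, 1L))
    },
    C = c(sample.int(E, 1L), 0L),
    E = c(E + sample.int(E, 1L), sample.int(E, 1L)),
    F = {
      a <- E + sample.int(E, 1L)
      c(a, E + sample.int(a - E, 1L))
    },
    G = {
      a <- sample.int(E, 1L)
      c(a, sample.int(a, 1L))
    },
    H = c(sample.int(E, 1L), 0L),
    domain_error("Unknown situation label `%s`.", situation)
  )
}

# Annual indicator values for a reporting area: Poisson service counts with
# some indicators unreported; drawn zeros are rendered blank with probability
# blank_zero_rate. At least one non-blank value is guaranteed (the situations
# that reach here all require CPC > 0).
draw_indicators <- function(n_ind, blank_zero_rate) {
  v <- stats::rpois(n_ind, lambda = 6)
  unreported <- stats::runif(n_ind) < 0.25
  zero_blank <- v == 0L & stats::runif(n_ind) < blank_zero_rate
  v[unreported | zero_blank] <- NA_integer_
  if (all(is.na(v))) v[1L] <- stats::rpois(1L, lambda = 6) + 1L
  as.integer(v)
}

#' Inject duplicate facility-year rows into synthetic extracts
#'
#' Duplicates whole facility-years (all six area rows in both extracts).
#' Scenario 1 copies carry different Reporting Rate / Reporting Rate on Time
#' data: one area with nonzero submissions is re-drawn within the same
#' situation class, so the injected situation label stays recoverable while
#' the rates differ. Scenario 2 copies are verbatim. Scenario-1 injection is
#' restricted to facility-years with at least one area with submissions
#' (rates of an all-zero record cannot differ). Row order of both extracts is
#' then shuffled deterministically; with both rates zero the extracts are
#' returned unchanged.
#'
#' @param extracts Output of [generate_extracts()].
#' @param config The same [generator_config()].
#' @return List like `extracts` with duplicated rows appended and `truth`
#'   updated: members of duplicate groups carry `is_duplicate` set to the
#'   scenario, copies have `is_copy = TRUE`.
#' @export
inject_duplicates <- function(extracts, config) {
  stopifnot(inherits(config, "generator_config"))
  rep_x <- extracts$reporting
  ind_x <- extracts$indicators
  truth <- extracts$truth
  keys <- dplyr::distinct(rep_x[c("facility_name", "county", "year")])
  n_keys <- nrow(keys)
  n1 <- round(config$dup_scenario1_rate * n_keys)
  n2 <- round(config$dup_scenario2_rate * n_keys)
  if (n1 + n2 == 0) {
    return(extracts)
  }
  key_id <- function(df) paste(df$facility_name, df$county, df$year, sep = "\r")
  keys$id <- key_id(keys)
  eligible1 <- keys$id[vapply(split(rep_x$actual_reports, key_id(rep_x))[keys$id],
                              function(a) any(a > 0), logical(1))]
  if (n1 > length(eligible1)) {
    config_error(
      "dup_scenario1_rate",
      "requires more perturbable facility-year rows than are available"
    )
  }
  if (n1 + n2 > n_keys) {
    config_error(
      "dup_scenario2_rate",
      "duplicate rates exceed the available facility-year rows"
    )
  }
  picked <- with_seed(child_seed(config$seed, 0L, 0L, 7L), {
    s1 <- sample(eligible1, n1)
    s2 <- sample(setdiff(keys$id, s1), n2)
    list(s1 = s1, s2 = s2)
  })

  rep_ids <- key_id(rep_x)
  ind_ids <- key_id(ind_x)
  truth_ids <- key_id(truth)

  rep_new <- list()
  ind_new <- list()
  truth_new <- list()
  add_copies <- function(ids, scen, perturb) {
    for (kx in seq_along(ids)) {
      id <- ids[kx]
      rep_copy <- rep_x[rep_ids == id, ]
      ind_copy <- ind_x[ind_ids == id, ]
      truth_copy <- truth[truth_ids == id, ]
      if (perturb) {
        cand <- which(rep_copy$actual_reports > 0)
        ai <- cand[1L]
        sit <- truth_copy$situation[match(rep_copy$area_code[ai], truth_copy$area_code)]
        E <- config$expected_reports_per_year
        orig <- c(rep_copy$actual_reports[ai], rep_copy$actual_on_time[ai])
        new <- with_seed(child_seed(config$seed, kx, 0L, 8L), {
          repeat {
            cnt <- draw_counts(sit, E)
            if (!identical(cnt, orig)) break
          }
          cnt
        })
        rep_copy$actual_reports[ai] <- new[1L]
        rep_copy$actual_on_time[ai] <- new[2L]
        rep_copy$reporting_rate_pct[ai] <- 100 * new[1L] / E
        rep_copy$reporting_rate_on_time_pct[ai] <- 100 * new[2L] / E
      }
      truth_copy$is_duplicate <- scen
      truth_copy$is_copy <- TRUE
      rep_new[[length(rep_new) + 1L]] <<- rep_copy
      ind_new[[length(ind_new) + 1L]] <<- ind_copy
      truth_new[[length(truth_new) + 1L]] <<- truth_copy
    }
    truth$is_duplicate[truth_ids %in% ids] <<- scen
  }
  add_copies(picked$s1, "scenario1", perturb = TRUE)
  add_copies(picked$s2, "scenario2", perturb = FALSE)
  rep_x <- dplyr::bind_rows(c(list(rep_x), rep_new))
  ind_x <- dplyr::bind_rows(c(list(ind_x), ind_new))
  truth <- dplyr::bind_rows(c(list(truth), truth_new))

  with_seed(child_seed(config$seed, 0L, 0L, 9L), {
    rep_x <- rep_x[sample.int(nrow(rep_x)), ]
    ind_x <- ind_x[sample.int(nrow(ind_x)), ]
  })
  list(reporting = rep_x, indicators = ind_x, truth = truth)
}

#' Write synthetic source files
#'
#' Writes the four delimited-text source files consumed by the ingest stage:
#' `reporting_extract.csv`, `indicator_extract.csv`, `facility_list.csv` and
#' `emr_list.csv`. Blank indicator cells are written as empty fields, never as
#' the text "NA", mirroring how the source system renders entered zeros.
#'
#' @param registry Facility registry tibble (with `has_emr`).
#' @param extracts Output of [generate_extracts()] or [inject_duplicates()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_sources <- function(registry, extracts, out_dir) {
  if (is.null(registry) || nrow(registry) == 0) {
    config_error("registry", "is empty; nothing to write")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) io_error("Cannot create output directory `%s`.", out_dir)
  paths <- c(
    reporting = file.path(out_dir, "reporting_extract.csv"),
    indicators = file.path(out_dir, "indicator_extract.csv"),
    facilities = file.path(out_dir, "facility_list.csv"),
    emr = file.path(out_dir, "emr_list.csv")
  )
  readr::write_csv(extracts$reporting, paths[["reporting"]], na = "")
  readr::write_csv(extracts$indicators, paths[["indicators"]], na = "")
  readr::write_csv(
    registry[c("facility_name", "county", "level", "facility_type", "ownership")],
    paths[["facilities"]],
    na = ""
  )
  readr::write_csv(
    registry[registry$has_emr, c("facility_name", "county")],
    paths[["emr"]],
    na = ""
  )
  invisible(paths)
}
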