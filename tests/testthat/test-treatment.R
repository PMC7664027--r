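test_that("facility-years with all-zero averages are excluded", {
  # the canonical examples: two all-zero facility-years and one reporting one
  recs <- record_table(
    record_row(facility = "Facility A", year = 2016),
    record_row(facility = "Facility B", year = 2016),
    record_row(facility = "Facility C", year = 2017,
               HCT = c(10, 90, 80), BS = c(100, 90, 80),
               default = c(50, 60, 50))
  )
  res <- drop_nonreporting_facility_years(recs)
  expect_equal(res$report$n_in, 3)
  expect_equal(res$report$n_removed, 2)
  expect_identical(res$kept$facility_name, "Facility C")
  expect_equal(nrow(res$audit), 2)
  # empty input passes through with a zero-count report
  res0 <- drop_nonreporting_facility_years(recs[0, ])
  expect_equal(res0$report$n_in, 0)
  expect_equal(res0$report$n_out, 0)
})

test_that("records with impossible rates are excluded whole", {
  recs <- record_table(
    record_row(facility = "e", PMTCT = c(25, 108.3, 50), default = c(50, 50, 25)),
    record_row(facility = "ok", default = c(50, 50, 25)),
    record_row(facility = "errx", BS = c(10, 50, 60), default = c(50, 50, 25))
  )
  res <- drop_erroneous(recs)
  expect_identical(res$kept$facility_name, "ok")
  expect_equal(res$report$n_removed, 2)
})

test_that("duplicate treatment deletes conflicting groups and keeps one identical copy", {
  base <- record_row(facility = "dup2", year = 2012, default = c(50, 50, 25))
  s2 <- record_table(base,
                     dplyr::mutate(base, occ = 2L),
                     dplyr::mutate(base, occ = 3L))
  s1a <- record_row(facility = "dup1", year = 2012, default = c(50, 50, 25))
  s1b <- dplyr::mutate(s1a, occ = 2L, rr_HCT = 75)
  lone <- record_row(facility = "solo", year = 2012, default = c(50, 50, 25))
  recs <- record_table(s2, s1a, s1b, lone)
  res <- treat_duplicates(recs)
  # scenario 2 of 3 -> exactly one kept; scenario 1 of 2 -> both removed
  expect_equal(sum(res$kept$facility_name == "dup2"), 1)
  expect_equal(sum(res$kept$facility_name == "dup1"), 0)
  expect_equal(sum(res$kept$facility_name == "solo"), 1)
  expect_equal(attr(res$report, "n_scenario1"), 2L)
  expect_equal(attr(res$report, "n_scenario2"), 2L)
  # the kept scenario-2 row is the first by record key
  expect_equal(res$kept$occ[res$kept$facility_name == "dup2"], 1L)
  # no groups: identity
  resi <- treat_duplicates(record_table(lone))
  expect_equal(resi$report$n_removed, 0)
})

test_that("disaggregation fans out six per-area datasets with situations", {
  recs <- record_table(
    record_row(facility = "f1", HCT = c(50, 50, 25), default = c(0, 0, 0)),
    record_row(facility = "f2", default = c(50, 50, 25))
  )
  sets <- disaggregate_by_area(recs)
  expect_identical(names(sets), area_codes())
  expect_true(all(vapply(sets, nrow, integer(1)) == 2))
  # metadata identical across a facility's six area rows
  lv <- vapply(sets, function(s) s$level[s$facility_name == "f1"], character(1))
  expect_true(all(lv == "II"))
  # situation recomputed per row matches direct classification of its triple
  for (s in sets) {
    expect_identical(s$situation, classify_situation(s$cpc, s$rr, s$rrt))
  }
})

test_that("situation treatment retains only G and H with full counts", {
  mk <- function(sit, n) {
    tibble::tibble(
      facility_key = sprintf("f%d|c", seq_len(n)), facility_name = "f",
      county = "c", year = 2011L, area_code = "HCT",
      cpc = switch(sit, A = 0, B = 0, G = 50, H = 50),
      rr = switch(sit, A = 0, B = 50, G = 50, H = 50),
      rrt = switch(sit, A = 0, B = 25, G = 25, H = 0),
      situation = sit
    )
  }
  ds <- dplyr::bind_rows(mk("A", 2), mk("B", 1), mk("G", 5), mk("H", 2))
  res <- apply_situation_treatment(ds)
  expect_equal(nrow(res$kept), 7)
  expect_equal(res$counts[["A"]], 2L)
  expect_equal(res$counts[["B"]], 1L)
  expect_equal(res$counts[["G"]], 5L)
  expect_equal(res$counts[["H"]], 2L)
  # all-B dataset empties; all-G dataset is untouched
  expect_equal(nrow(apply_situation_treatment(mk("B", 4))$kept), 0)
  expect_equal(nrow(apply_situation_treatment(mk("G", 4))$kept), 4)
})

test_that("cleaning cycles conserve records and chain their counts", {
  cfg <- generator_config(n_facilities = 80, years = 2011:2014, seed = 29,
                          dup_scenario1_rate = 0.02, dup_scenario2_rate = 0.02)
  case <- build_synthetic_case(cfg)
  res <- run_cleaning_cycles(case$merged$records)
  cyc <- res$cycles
  expect_true(all(cyc$n_in == cyc$n_removed + cyc$n_out))
  # record-level cycles chain: cycle k feeds cycle k+1
  rec_cycles <- cyc[1:3, ]
  expect_equal(rec_cycles$n_in[-1], rec_cycles$n_out[-3])
  # per-area cycles all start from the post-duplicate record count
  area_cycles <- cyc[4:9, ]
  expect_true(all(area_cycles$n_in == rec_cycles$n_out[3]))
  # conservation at area granularity: 6 x initial = 6 x record removals
  # + per-area removals + retained
  initial <- nrow(case$merged$records)
  record_removed <- sum(rec_cycles$n_removed)
  area_removed <- sum(area_cycles$n_removed)
  retained <- sum(vapply(res$area_datasets, nrow, integer(1)))
  expect_equal(6 * initial, 6 * record_removed + area_removed + retained)
  # the audit log holds one entry per removed record
  expect_equal(nrow(res$audit), record_removed + area_removed)
  # clean-in, clean-out: an all-G world loses nothing
  mixG <- stats::setNames(rep(list(c(G = 1)), 6), area_codes())
  cfgG <- generator_config(n_facilities = 20, years = 2011:2012, seed = 5,
                           situation_mix = mixG, facility_a_rate = 0,
                           dup_scenario1_rate = 0, dup_scenario2_rate = 0)
  caseG <- build_synthetic_case(cfgG)
  resG <- run_cleaning_cycles(caseG$merged$records)
  expect_true(all(resG$cycles$n_removed == 0))
  # an all-A world is fully removed at the first cycle
  mixA <- stats::setNames(rep(list(c(A = 1)), 6), area_codes())
  cfgA <- generator_config(n_facilities = 20, years = 2011:2012, seed = 5,
                           situation_mix = mixA, facility_a_rate = 1,
                           dup_scenario1_rate = 0, dup_scenario2_rate = 0)
  caseA <- build_synthetic_case(cfgA)
  resA <- run_cleaning_cycles(caseA$merged$records)
  expect_equal(resA$cycles$n_removed[1], nrow(caseA$merged$records))
  expect_equal(resA$cycles$n_out[1], 0)
})

test_that("re-cleaning the pipeline's own output removes nothing", {
  cfg <- generator_config(n_facilities = 80, years = 2011:2014, seed = 31,
                          dup_scenario1_rate = 0.02, dup_scenario2_rate = 0.02)
  case <- build_synthetic_case(cfg)
  res <- run_cleaning_cycles(case$merged$records)
  # record-level stages are idempotent on the post-duplicate record set
  clean_records <- res$records_clean
  expect_equal(drop_nonreporting_facility_years(clean_records)$report$n_removed, 0)
  expect_equal(drop_erroneous(clean_records)$report$n_removed, 0)
  expect_equal(treat_duplicates(clean_records)$report$n_removed, 0)
  # per-area treatment is idempotent on each clean area dataset
  for (a in area_codes()) {
    expect_equal(apply_situation_treatment(res$area_datasets[[a]])$report$n_removed, 0)
  }
})

test_that("cleaning recovers the injected truth exactly", {
  cfg <- generator_config(n_facilities = 50, years = 2011:2014, seed = 37,
                          dup_scenario1_rate = 0.03, dup_scenario2_rate = 0.03)
  case <- build_synthetic_case(cfg)
  res <- run_cleaning_cycles(case$merged$records)
  truth <- case$extracts$truth

  # classifier recovery: every merged area row classifies to its injected label
  long <- dplyr::bind_rows(disaggregate_by_area(case$merged$records))
  tkey <- truth_area_key(truth)
  tmap <- stats::setNames(truth$situation, tkey)
  lkey <- paste(long$facility_key, long$year, long$area_code, sep = "\r")
  expect_true(all(lkey %in% names(tmap)))
  expect_identical(long$situation, unname(tmap[lkey]))

  # retained set equals the truth-derived expectation
  expected <- expected_retained_from_truth(truth)
  got <- dplyr::bind_rows(res$area_datasets)
  expect_equal(nrow(got), nrow(expected))
  expect_identical(
    sort(paste(got$facility_key, got$year, got$area_code)),
    sort(paste(expected$facility_key, expected$year, expected$area_code))
  )
})
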