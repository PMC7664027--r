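uniform_mix <- function(w) {
  stats::setNames(rep(list(w / sum(w)), 6), area_codes())
}

test_that("generator config validates its fields", {
  expect_s3_class(generator_config(n_facilities = 3, seed = 1), "generator_config")
  expect_error(generator_config(n_facilities = 0), class = "dhisclean_config_error")
  expect_error(generator_config(n_facilities = 2, years = c(2012, 2011)),
               class = "dhisclean_config_error")
  expect_error(generator_config(n_facilities = 2, blank_zero_rate = 1.2),
               class = "dhisclean_config_error")
  bad_mix <- stats::setNames(rep(list(c(A = 0.5, G = 0.6)), 6), area_codes())
  expect_error(generator_config(n_facilities = 2, situation_mix = bad_mix),
               class = "dhisclean_config_error")
  # error message names the offending field
  expect_error(generator_config(n_facilities = 0), "n_facilities")
})

test_that("facility registry is deterministic with valid domains", {
  cfg <- generator_config(n_facilities = 30, seed = 5)
  reg <- generate_facility_registry(cfg)
  expect_equal(nrow(reg), 30)
  expect_false(any(duplicated(reg$facility_name)))
  expect_true(all(reg$level %in% c("II", "III", "IV", "V", "VI")))
  expect_true(all(reg$county %in% default_counties()))
  expect_identical(reg, generate_facility_registry(cfg))
  # growing the population does not reshuffle earlier facilities
  reg_big <- generate_facility_registry(generator_config(n_facilities = 40, seed = 5))
  expect_identical(reg_big[1:30, ], reg)
})

test_that("degenerate mixtures force their situation patterns", {
  base <- function(mix) {
    generator_config(
      n_facilities = 12, years = 2011:2012, situation_mix = mix,
      facility_a_rate = 0, dup_scenario1_rate = 0, dup_scenario2_rate = 0,
      seed = 3
    )
  }
  areas <- programmatic_areas()
  nonblank_per_row <- function(ex) {
    m <- as.matrix(ex$indicators[dhisclean:::indicator_col_names()])
    rowSums(!is.na(m))
  }

  # all-G: ideal reporting everywhere
  cfg <- base(uniform_mix(c(G = 1)))
  ex <- generate_extracts(generate_facility_registry(cfg), cfg)
  expect_true(all(ex$reporting$reporting_rate_pct > 0))
  expect_true(all(ex$reporting$reporting_rate_pct <= 100))
  expect_true(all(ex$reporting$reporting_rate_on_time_pct > 0))
  expect_true(all(ex$reporting$reporting_rate_on_time_pct <=
                    ex$reporting$reporting_rate_pct))
  expect_true(all(nonblank_per_row(ex) >= 1))

  # all-A: nothing reported anywhere
  cfg <- base(uniform_mix(c(A = 1)))
  ex <- generate_extracts(generate_facility_registry(cfg), cfg)
  expect_true(all(ex$reporting$actual_reports == 0))
  expect_true(all(ex$reporting$actual_on_time == 0))
  expect_true(all(nonblank_per_row(ex) == 0))

  # all-F: both rates strictly above 100
  cfg <- base(uniform_mix(c(F = 1)))
  ex <- generate_extracts(generate_facility_registry(cfg), cfg)
  expect_true(all(ex$reporting$reporting_rate_pct > 100))
  expect_true(all(ex$reporting$reporting_rate_on_time_pct > 100))
  expect_true(all(ex$reporting$reporting_rate_pct <= 200))
})

test_that("emitted counts and percentages are coherent for every row", {
  cfg <- generator_config(n_facilities = 40, seed = 9,
                          dup_scenario1_rate = 0, dup_scenario2_rate = 0)
  ex <- generate_extracts(generate_facility_registry(cfg), cfg)
  expect_equal(ex$reporting$reporting_rate_pct,
               100 * ex$reporting$actual_reports / ex$reporting$expected_reports)
  expect_equal(ex$reporting$reporting_rate_on_time_pct,
               100 * ex$reporting$actual_on_time / ex$reporting$expected_reports)
  # one truth label per emitted area record
  expect_equal(nrow(ex$truth), nrow(ex$reporting))
})

test_that("empirical situation frequencies recover the mixture", {
  mix <- uniform_mix(c(A = 0.1, B = 0.15, C = 0.05, D = 0.1, G = 0.45, H = 0.15))
  cfg <- generator_config(
    n_facilities = 300, years = 2011:2018, situation_mix = mix,
    facility_a_rate = 0, dup_scenario1_rate = 0, dup_scenario2_rate = 0,
    seed = 17
  )
  ex <- generate_extracts(generate_facility_registry(cfg), cfg)
  n <- 300 * 8
  for (a in area_codes()) {
    freq <- table(factor(ex$truth$situation[ex$truth$area_code == a],
                         levels = names(mix[[a]]))) / n
    for (s in names(mix[[a]])) {
      p <- mix[[a]][[s]]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(freq[[s]] - p), 3 * se + 1e-12)
    }
  }
})

test_that("duplicate injection copies rows per scenario and stays seeded", {
  cfg <- generator_config(
    n_facilities = 10, years = 2011L, facility_a_rate = 0,
    dup_scenario1_rate = 0, dup_scenario2_rate = 1, seed = 21
  )
  ex <- generate_extracts(generate_facility_registry(cfg), cfg)
  dup <- inject_duplicates(ex, cfg)
  # every facility-year duplicated verbatim: 20 facility-years, exact pairs
  keys <- paste(dup$reporting$facility_name, dup$reporting$year)
  expect_equal(length(unique(keys)), 10)
  expect_equal(nrow(dup$reporting), 2 * nrow(ex$reporting))
  pair_sizes <- dplyr::count(
    dup$reporting,
    facility_name, year, area_code,
    reporting_rate_pct, reporting_rate_on_time_pct
  )
  expect_true(all(pair_sizes$n == 2))

  # scenario 1 groups must differ in RR or RRT
  cfg1 <- generator_config(
    n_facilities = 10, years = 2011L, facility_a_rate = 0,
    dup_scenario1_rate = 0.5, dup_scenario2_rate = 0, seed = 21
  )
  ex1 <- generate_extracts(generate_facility_registry(cfg1), cfg1)
  dup1 <- inject_duplicates(ex1, cfg1)
  t1 <- dup1$truth[dup1$truth$is_duplicate == "scenario1", ]
  for (k in unique(paste(t1$facility_name, t1$year))) {
    rows <- dup1$reporting[paste(dup1$reporting$facility_name,
                                 dup1$reporting$year) == k, ]
    rates <- rows[c("area_code", "reporting_rate_pct", "reporting_rate_on_time_pct")]
    expect_gt(nrow(unique(rates)), 6) # at least one area differs between copies
  }

  # zero rates: identity
  cfg0 <- generator_config(n_facilities = 5, dup_scenario1_rate = 0,
                           dup_scenario2_rate = 0, seed = 2)
  ex0 <- generate_extracts(generate_facility_registry(cfg0), cfg0)
  expect_identical(inject_duplicates(ex0, cfg0), ex0)

  # determinism of the whole generation path
  expect_identical(dup1, inject_duplicates(generate_extracts(
    generate_facility_registry(cfg1), cfg1), cfg1))
})

test_that("written sources round-trip exactly and render blanks as empty", {
  cfg <- generator_config(n_facilities = 15, years = 2011:2013, seed = 33,
                          dup_scenario1_rate = 0.05, dup_scenario2_rate = 0.05)
  case <- build_synthetic_case(cfg)
  rep_in <- read_reporting_extract(case$paths[["reporting"]])
  expect_equal(nrow(rep_in), nrow(case$extracts$reporting))
  expect_equal(sort(rep_in$reporting_rate_pct),
               sort(case$extracts$reporting$reporting_rate_pct))
  # blank indicator cells are empty fields, never the text "NA"
  raw <- readLines(case$paths[["indicators"]])
  expect_false(any(grepl(",NA,|,NA$", raw)))
  # byte-identical regeneration from the same config
  dir2 <- withr::local_tempdir()
  reg2 <- generate_facility_registry(cfg)
  ex2 <- inject_duplicates(generate_extracts(reg2, cfg), cfg)
  paths2 <- write_sources(reg2, ex2, dir2)
  for (f in names(paths2)) {
    expect_identical(readLines(paths2[[f]]), readLines(case$paths[[f]]))
  }
  # empty registry refuses to write
  expect_error(write_sources(case$registry[0, ], case$extracts, withr::local_tempdir()),
               class = "dhisclean_config_error")
})

test_that("entered zeros are rendered blank at rate one", {
  cfg <- generator_config(n_facilities = 30, years = 2011L, seed = 12,
                          facility_a_rate = 0, blank_zero_rate = 1,
                          dup_scenario1_rate = 0, dup_scenario2_rate = 0)
  ex <- generate_extracts(generate_facility_registry(cfg), cfg)
  m <- as.matrix(ex$indicators[dhisclean:::indicator_col_names()])
  expect_false(any(m == 0, na.rm = TRUE))
  # with blanking off, zeros survive as explicit values
  cfg0 <- generator_config(n_facilities = 30, years = 2011L, seed = 12,
                           facility_a_rate = 0, blank_zero_rate = 0,
                           dup_scenario1_rate = 0, dup_scenario2_rate = 0)
  ex0 <- generate_extracts(generate_facility_registry(cfg0), cfg0)
  m0 <- as.matrix(ex0$indicators[dhisclean:::indicator_col_names()])
  expect_true(any(m0 == 0, na.rm = TRUE))
})
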