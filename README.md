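# dhisclean

Systematic, audited cleaning of aggregate HIV-indicator facility reports
extracted from DHIS2-style national reporting systems.

National platforms such as DHIS2 collect monthly programmatic-area reports
from thousands of health facilities. Extracts of these data are reused for
secondary analyses — but they contain facilities that never report, empty
reports submitted to satisfy form requirements, indicator data with no
recorded submission rates, logically impossible reporting rates above 100%,
and duplicated facility-years. `dhisclean` is for monitoring-and-evaluation
teams and researchers who need such extracts cleaned *transparently*: every
record that is removed is accounted for, by rule, in an audit trail.

## What it computes

For each facility, year and programmatic area (Kenya's six HIV areas: HCT,
PMTCT, CrT, VMMC, PEP, BS, with 14/40/65/13/14/3 indicators and 12 expected
monthly reports per area-year) the pipeline evaluates three percentages:

* **RR** — Reporting Rate, `100 · submitted / expected`;
* **RRT** — Reporting Rate on Time, `100 · on_time / expected`;
* **CPC** — Cumulative Percent Completion,
  `100 · non-blank indicator values / total indicators` in the annual area
  report (an explicit zero counts as reported; DHIS2 renders zeros as
  blanks).

Each (CPC, RR, RRT) triple is diagnosed into a situation: **A** (nothing
reported), **B**/**C** (empty reports, on time / late), **D** (data without
rates), **E**/**F** (rates above 100%), **G** (ideal), **H** (complete but
late), plus **ERR_X** for internally inconsistent timeliness (RRT > RR).
Treatment proceeds in audited cycles — non-reporting facility-years, then
erroneous records, then duplicates (conflicting copies all removed,
identical copies deduplicated), then per-area retention of situations G and
H only — followed by a distribution analysis across areas with Friedman and
post hoc Wilcoxon signed-rank tests (normal approximation, no continuity
correction, exact small-n tail reported alongside).

A seeded synthetic-data generator emulates DHIS2 extracts with injected,
labelled anomalies, so the whole pipeline is testable without access to a
national database. See the methods vignette
(`vignettes/cleaning-methodology.Rmd`) for the full model and design
decisions.

## Worked example

```r
library(dhisclean)

cfg <- generator_config(n_facilities = 200, years = 2011:2018, seed = 7,
                        dup_scenario1_rate = 0.005, dup_scenario2_rate = 0.005)
registry <- generate_facility_registry(cfg)
extracts <- inject_duplicates(generate_extracts(registry, cfg), cfg)
paths    <- write_sources(registry, extracts, "example")

merged <- merge_sources(read_reporting_extract(paths[["reporting"]]),
                        read_indicator_extract(paths[["indicators"]]),
                        read_facility_list(paths[["facilities"]], paths[["emr"]]))
res <- run_cleaning_cycles(merged$records)
res$cycles
#> # A tibble: 9 × 5
#>   cycle_id rule                        n_in n_removed n_out
#>      <int> <chr>                      <int>     <int> <int>
#> 1        1 nonreporting_facility_year  1616       803   813
#> 2        2 erroneous_rates              813         0   813
#> 3        3 duplicates                   813        21   792
#> 4        4 situation_treatment_HCT      792        52   740
#> ...
```

1,616 facility-year records enter (200 facilities × 8 years, plus 16
injected duplicates); 803 carried no data at all and are removed first;
duplicate treatment removes 21 rows; per-area treatment then retains only
G/H rows in each area's dataset. Cycle counts always satisfy
`n_in = n_removed + n_out`.

```r
situation_distribution(res$situation_counts, res$dup_removed, res$dataset4_n)
#> # A tibble: 12 × 7
#>    situation            HCT PMTCT   CrT  VMMC   PEP    BS
#>  1 A                   1.72  6.77 50.9  93.7  59.8  95.6
#>  2 B                   2.95  5.9   0.86  1.23 17.3   1.48
#>  ...
#> 12 total_retained_pct 91.0  81.2  42.8   0.25 18.9   0.37
```

Percentages are of "dataset 4" (the records entering duplicate treatment);
each area column sums to 100 and `total_retained_pct = pct(G) + pct(H)` —
here 91% of HCT records survive cleaning but only 0.25% of VMMC records,
since few facilities offer that service.

```r
mB <- per_year_counts(res$pre_treatment_areas, "B")   # empty reports, by year x area
friedman_test(mB)
#> Friedman rank analysis of variance
#>   chi-squared = 25.6554, df = 5, p = 0.0001041
#>   mean ranks:
#>   HCT PMTCT   CrT  VMMC   PEP    BS
#>  3.62  4.56  2.06  2.38  5.81  2.56

wilcoxon_signed_rank(mB[, "PEP"], mB[, "HCT"])
#> Wilcoxon signed-rank test (normal approximation)
#>   W = 0, Z = -2.3664, p = 0.01796 (exact p = 0.01563)
```

The Friedman test (ranks ascending, so the most-affected area has the
highest mean rank) shows that the burden of empty submitted reports differs
significantly across areas, with PEP worst (mean rank 5.81 of a possible
6); the post hoc Wilcoxon comparison of PEP against HCT confirms the
difference (`posthoc_pairwise(mB)` runs all 15 pairs).

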