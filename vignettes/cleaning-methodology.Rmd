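---
title: "Screening, diagnosis and treatment of DHIS2 facility-report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, diagnosis and treatment of DHIS2 facility-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhisclean)
```

## The problem

National aggregate reporting platforms such as DHIS2 receive monthly
programmatic-area reports from thousands of health facilities. Kenya's
comprehensive HIV reporting form comprises six independent area reports —
HIV Counselling and Testing (HCT, 14 indicators), Prevention of
Mother-to-Child Transmission (PMTCT, 40), Care and Treatment (CrT, 65),
Voluntary Medical Male Circumcision (VMMC, 13), Post-Exposure Prophylaxis
(PEP, 14) and Blood Safety (BS, 3) — each expected twelve times per facility
per year. Extracts of these data are widely reused for secondary analyses,
but they arrive dirty: facilities that never report, empty reports submitted
to satisfy form requirements, indicator data with no recorded submission
rates, rates above 100%, and duplicated facility-years. `dhisclean`
implements a systematic, fully audited cleaning pipeline for such extracts,
organised as repeated cycles of *screening* (compute the evaluation
variables), *diagnosis* (classify each record into a situation taxonomy) and
*treatment* (exclude or retain, with complete accounting).

## Evaluation variables

Three per-area, per-year percentages drive the diagnosis:

* **Reporting Rate** `RR = 100 * submitted / expected`, with `expected = 12`
  monthly reports per area-year. RR measures submission only, not content.
* **Reporting Rate on Time** `RRT = 100 * on_time / expected`.
* **Cumulative Percent Completion**
  `CPC = 100 * non-blank indicator values / total indicators` in the annual
  area report. A facility reporting 10 of PMTCT's 40 indicators scores 25%.

CPC exists because RR is blind to content: DHIS2 renders entered zeros as
blank cells, so a submitted-but-empty report counts as "complete" by RR
alone. An explicit zero counts as non-blank in CPC; by construction CPC lies
in [0, 100]. RR and RRT are deliberately *not* clipped at 100 — above-100%
values are the fingerprint of erroneous records and must survive ingestion
to be diagnosed. Nothing is rounded internally; presentation tables round to
two decimals.

## The situation taxonomy

Each (CPC, RR, RRT) triple maps to one label (`classify_situation()`,
`situation_table()`):

| label | pattern | diagnosis | action |
|---|---|---|---|
| A | 0, 0, 0 | nothing reported | exclude |
| B | 0, X, X | empty reports, some on time | exclude |
| C | 0, X, 0 | empty reports, none on time | exclude |
| D | X, 0, 0 | indicator data, no rates recorded | exclude |
| E | X, >100, X | impossible submission rate | exclude |
| F | X, >100, >100 | both rates impossible | exclude |
| G | X, X, X | ideal | include |
| H | X, X, 0 | complete but late | include |
| ERR_X | RRT > RR or RRT > 100 (RR ≤ 100) | timeliness inconsistent | exclude |

Branch precedence is fixed: F, then E, then ERR_X, then the zero-pattern
labels. Two corners of the input space are not covered by the base taxonomy
and needed a decision. First, an RR above 100 routes to E/F regardless of
CPC, because the "not logically possible" rationale does not depend on
content. Second, a triple whose RRT exceeds its RR (or exceeds 100 while RR
is in range) is impossible for the same reason — on-time reports are a
subset of submitted reports — but matches no base row; those get the
`ERR_X` extension and are excluded. With these two rules the nine branches
partition all non-negative triples: a property test classifies 10^5 random
triples and checks totality and order-independence.

## Cleaning cycles

`run_cleaning_cycles()` executes, by default in this order:

1. **Non-reporting facility-years** — records whose average CPC, RR and RRT
   over the six areas are all zero are removed. Missing components from
   one-sided merges are treated as zero in the averages (the raw `NA` is
   kept in the record for audit).
2. **Erroneous records** — any record with an area in E, F or ERR_X is
   removed whole. This is record-level exclusion: a G area inside such a
   record is removed with it, the record being untrustworthy.
3. **Duplicates** — rows sharing normalized facility name, county and year.
   Groups with conflicting RR/RRT data (scenario 1) are removed entirely;
   identical groups (scenario 2) keep one representative (first in a stable
   sort by record key). Comparison is exact, with no numeric tolerance,
   since duplicates originate from the same export.
4. **Per-area situation treatment** — the survivors are disaggregated into
   six per-area datasets and only G and H rows are retained.

The ordering of the three record-level cycles is configurable; the default
reflects the natural narrative (no-data records first, then impossible
rates, then duplicates). Every cycle emits an accounting row satisfying
`n_in = n_removed + n_out`, consecutive cycles chain, and every removed
record is logged with its key, cycle, rule and reason. "Dataset 4" — the
record set entering duplicate treatment — is kept as the denominator of the
distribution analysis, so that situation percentages, the duplicates row and
the retained percentage of each area sum to exactly 100.

Re-cleaning the pipeline's own output removes nothing: the record-level
stages are idempotent on their record output and the per-area treatment is
idempotent on each clean area dataset. (A full re-run from the per-area
output is not meaningful, because the pipeline's final product is six
per-area datasets rather than a record table.)

A complementary **frequency screen** (`frequency_screen()`) flags facilities
with more annual reports in one area than the study's year span (more than
8 in a 2011–2018 window) — an independent route to duplicates, run where
duplicates are still present (the disaggregation of dataset 4). The
threshold is parameterized as the span length, not hard-coded.

## Distribution analysis and rank tests

`situation_distribution()` reports, per area, the percentage of dataset-4
records in each situation, duplicates included, with derived
`total_retained_pct = pct(G) + pct(H)`. An area with a zero denominator is
reported as undefined, not zero.

For selected situations (B and D by default), `per_year_counts()` builds a
years × areas count matrix and:

* `friedman_test()` ranks areas **ascending** within each year — the
  most-affected area gets the highest rank, so an area strictly largest in
  all 8 years attains mean rank 6.00 — and computes the tie-corrected
  chi-square statistic
  `(k−1) Σ(R_j − N(k+1)/2)² / (Σ r_ij² − N k (k+1)²/4)` with k−1 degrees of
  freedom (the uncorrected variant is reported alongside; the corrected one
  is the default and matches `stats::friedman.test`). Degenerate all-equal
  input yields statistic 0 and p = 1.
* `posthoc_pairwise()` runs `wilcoxon_signed_rank()` on all 15 unordered
  area pairs. The Wilcoxon implementation drops zero differences, ranks
  absolute differences with average ties, takes `W = min(W⁺, W⁻)` and
  `Z = (W − n(n+1)/4) / √(n(n+1)(2n+1)/24 − Σ(t³−t)/48)` — the normal
  approximation **without** continuity correction, which for n = 8 same-sign
  distinct differences gives the characteristic |Z| = 18/√51 = 2.521. Z is
  reported from the smaller rank-sum side and is therefore never positive.
  When the non-zero differences are untied, the exact signed-rank tail is
  reported alongside: at n = 8, W = 0 it is 2/2⁸ = 0.0078, against 0.0117
  from the normal approximation — the gap is the expected small-sample
  approximation error, which is why both are shown. Each pair carries a
  direction summary ("Higher in X for m years", m = years in which X's
  count strictly exceeds the other's). Raw p-values are reported; a
  Bonferroni option exists but is off by default, matching common post hoc
  reporting practice for this design.

The Friedman p-value is validated against an exhaustive permutation oracle
on 3 blocks × 3 treatments (all 6³ within-block rank assignments); at that
size the chi-square approximation is known to be rough, and the test suite
allows a 0.15 absolute gap, the magnitude typical of exact-vs-asymptotic
differences at N = 3.

## The synthetic generator

Real extracts live in an access-restricted national database, so the
package ships a generator (`generator_config()`, `generate_extracts()`,
`inject_duplicates()`, `write_sources()`) that emulates the statistical
structure the pipeline assumes and attaches a ground-truth label to every
emitted record, making every stage testable end to end.

Design choices, fixed once:

* **Study conditions.** Six areas with 14/40/65/13/14/3 indicators, years
  2011–2018, 12 expected monthly reports per area-year, 47 counties.
* **Situation mixtures.** One mixture per area over labels A–H. The defaults
  place roughly half of facility-years as facility-level non-reporters
  (all six areas A simultaneously, via a distinct `facility_a_rate = 0.5`
  weight, so all-zero records like the taxonomy's Facility A/B examples
  exist), and set per-area conditional mixtures that reproduce the broad
  published structure of cleaned national HIV reporting — HCT/PMTCT
  dominated by ideal reporting, VMMC/BS dominated by non-service provision,
  PEP heavy in empty submitted reports — with above-100% errors at about
  0.03% in total. Within a reporting facility-year, areas draw
  independently; the real joint distribution across areas is unknown, and
  independence is an explicit modelling assumption.
* **Pattern fidelity by construction.** Counts are drawn inside each
  situation's constraints (e.g. G: `submitted ∈ 1..12`,
  `on_time ∈ 1..submitted`; E/F: `submitted ∈ 13..24`, putting RR uniformly
  on (100, 200] — magnitudes above 100 are otherwise unconstrained by the
  situation patterns), and percentages are always `100 × count / expected`,
  so re-classifying any emitted record recovers its injected label exactly.
  Situation D is generated by zeroing the submission counts while keeping
  indicator data — reproducing the observable pattern of the merge
  inconsistency without modelling its unknown origin.
* **Blanks.** Indicator values are Poisson service counts with a 25%
  unreported rate; a drawn zero is rendered blank with probability
  `blank_zero_rate` (default 1, matching the platform's zeros-as-blanks
  rendering). Reporting situations guarantee at least one non-blank value.
* **Duplicates.** Whole facility-years are copied. Scenario-2 copies are
  verbatim. Scenario-1 copies re-draw one area's counts *within the same
  situation class* (guaranteed different), so rates conflict while truth
  labels stay recoverable; scenario 1 is therefore only injected on
  facility-years with at least one area with submissions. Row order is then
  shuffled deterministically.
* **Reproducibility.** One root seed; child streams per (facility, year,
  area) derived by counter, so enlarging the facility population does not
  reshuffle earlier facilities, and identical configurations produce
  byte-identical source files.

What the generator does **not** emulate: monthly report timestamps (the
pipeline works from annual cumulative extracts), realistic epidemiological
indicator magnitudes, facility-name spelling noise between the master list
and the extracts, and any cross-area dependence beyond the facility-level
non-reporter draw. Passing recovery tests therefore demonstrate that the
pipeline implements its rules exactly — not that those rules capture every
pathology of real national data.

## Problem sizes and numerical choices

The test suite exercises the full chain at 2,000 synthetic facility-years
(250 facilities × 8 years) for exact truth recovery, and 5,000 facility-years
per area (625 × 8) for mixture recovery, where empirical situation
frequencies must fall within 3 binomial standard errors of the configured
mixture — sizes chosen to make binomial noise small relative to the
mixture weights while keeping a full run in tens of seconds. Facility
matching uses case-folded, whitespace-collapsed name + county; fuzzy
matching is out of scope. Missing triple components are coerced to zero only
at classification and averaging; the merge keeps the raw missingness for
audit, and the merge log records every one-sided join. Equality comparisons
for duplicate detection are exact. Per-area indicator counts are fixed
across years; extracts whose indicator sets change over time are not
supported.

## Limitations

The pipeline deletes rather than corrects: no imputation or adjustment for
incomplete reporting is attempted, and retained G/H records are used as-is.
Causal diagnosis of situations D, E and F is out of scope. The
record-level erroneous exclusion removes whole facility-years, so valid
areas inside an erroneous record are sacrificed by design. Published
whole-country headline figures depend on the restricted national extract
and are not reproducible from synthetic data; the package instead validates
the worked examples and analytically forced statistics of the method, plus
its own recovery and conservation properties.
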