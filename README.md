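# faersignal

Disproportionality signal detection for spontaneous adverse-event report
databases in the FAERS quarterly ASCII dialect.

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect voluntary reports of suspected adverse drug reactions. They
have no denominator of exposed patients, so drug safety signals are found by
*disproportionality analysis*: for a drug–event pair, compare how often the
event is reported with the drug against how often it is reported with every
other drug. `faersignal` implements this end to end for pharmacovigilance
analysts and methodologists:

- **Ingestion** of the "$"-delimited FAERS quarterly tables (DEMO, DRUG,
  REAC, THER, OUTC, INDI) with partial-date and missing-field handling, plus
  the user-supplied lookup CSVs (MedDRA PT→SOC map, IME list, drug-label
  list, drug synonyms).
- **Case deduplication** by the standard rule: one report per CASEID — the
  latest FDA_DT, ties broken by the higher PRIMARYID.
- **Cohort construction**: reports naming the target drug (by synonym list)
  as primary suspect.
- **Four estimators** on the 2×2 contingency table
  `a, b, c, d` (target-drug reports with/without the term, other reports
  with/without it, counted as distinct report–term pairs):

  | Method | Statistic | Signal criterion |
  |---|---|---|
  | ROR | `ad/bc`, Wald 95% CI | CI lower bound > 1 and `a ≥ 3` |
  | PRR | `[a/(a+b)]/[c/(c+d)]`, Pearson χ² | PRR ≥ 2, χ² ≥ 4, `a ≥ 3` |
  | BCPNN | information component IC (bits), closed-form posterior | IC025 > 0 |
  | MGPS | EBGM under a two-component gamma–Poisson mixture prior fitted by marginal maximum likelihood | EBGM ≥ 2 |

  A term is a **consensus signal** only if all four criteria hold.
- **Time to onset** (event date minus earliest target-drug therapy start;
  missing/negative intervals excluded) with median, IQR and day-bin
  proportions, and **demographic summaries** (sex, age groups, reporters,
  countries, outcomes, indications, reports per year).
- A **synthetic FAERS generator** with designed reporting-rate multipliers,
  injected duplicate case versions, and configurable date pathologies, so
  every stage is testable against known ground truth without licensed
  MedDRA/IME data or FAERS downloads.

## Worked example

Simulate a 20,000-case database in which the target drug multiplies the
background reporting rate of inflammatory bowel disease tenfold, then run
the full pipeline:

```r
library(faersignal)
library(dplyr)

sim <- simulate_faers(sim_config(
  n_cases = 20000, seed = 42,
  signal_spec = tibble::tibble(drug = "ISOTRETINOIN",
                               pt = "Inflammatory bowel disease",
                               multiplier = 10)))

lookups <- faers_lookups(
  pt_to_soc = default_pt_catalog()[, c("pt", "soc")],
  ime      = c("Inflammatory bowel disease", "Suicidal ideation"),
  label    = c("Lip dry", "Cheilitis", "Dry skin"),
  synonyms = "ISOTRETINOIN")

res <- run_faers_pipeline(pipeline_config(tables = sim$tables,
                                          lookups = lookups))
res
#> <faers_pipeline_result>
#>   clean cases: 2347
#>   PT terms analysed: 24 (consensus: 1)
#>   SOC terms analysed: 9 (consensus: 0)
#>   TTO included: 1003

res$signals_pt |> filter(consensus)
#>                         term   n  ror ror_lo ror_hi  prr   chi2 ebgm ebgm05   ic ic025
#> 1 Inflammatory bowel disease 470 9.52   8.29  10.93 8.76 1470.2  4.5   4.49 2.15  1.98

glance(res$tto_summary)
#>   n_cases n_included n_missing_date n_negative median_days    q1    q3
#> 1    2347       1003           1320         24          76    33   167
```

Reading the consensus row: the drug–IBD pair was reported 470 times among
the deduplicated report–event pairs, far above its expectation under
independence; the ROR of 9.5 (CI 8.3–10.9) recovers the designed multiplier
of 10, the empirical-Bayes geometric mean shrinks it toward the null (4.5),
and all four criteria agree, so the term is called a signal. It is the only
one of 24 analysed terms flagged — the other 23 have multiplier 1 by
construction. The onset summary reflects the generator's log-normal onset
distribution (designed median 81 days) after date exclusions.

`autoplot(res$signals_pt)`, `autoplot(res$tto_summary)` and
`plot_annual_reports(res$demographics)` draw the forest plot, the onset
histogram and the yearly report counts. A thin command-line wrapper with
`simulate` and `run` subcommands is installed at `inst/cli/faersignal.R`.

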