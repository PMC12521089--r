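---
title: "Methods: disproportionality signal detection in faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection in faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems collect voluntary reports of suspected adverse
drug reactions. Each report links demographic, drug, reaction, therapy-date,
outcome and indication records through a report identifier (PRIMARYID), and
successive versions of the same case appear under one CASEID. Because there
is no denominator of exposed patients, association between a drug and an
adverse event is assessed by disproportionality: does the drug–event pair
occur more often than expected if drug and event were reported
independently?

`faersignal` implements the full analysis pipeline for the FAERS quarterly
ASCII dialect, validated end-to-end on a synthetic generator with designed
ground truth.

## Cleaning model

**Deduplication.** Records are grouped by CASEID and the version with the
maximum FDA_DT is kept; among versions sharing that date, the maximum
PRIMARYID wins. A version with a missing or partial FDA_DT sorts below any
dated version: a dated version is strictly more recent/complete evidence.
This rule is deterministic, idempotent, and on synthetic data recovers the
generator's duplicate ledger exactly (zero false keeps or drops, asserted in
the test suite).

**Cohort.** A report enters the drug cohort iff some DRUG row matches a
synonym — uppercased, trimmed, exact equality against `drugname` or
`prod_ai` — with role code `PS` (primary suspect). Exact matching is the
default because FAERS free-text drug names make substring matching
high-recall/low-precision; substring mode and other roles are opt-in
configuration, since real analyses differ in how aggressively they search
the free-text names.

**Term standardisation.** Reaction terms are MedDRA Preferred Terms (PTs).
The PT→System Organ Class map, the Important-Medical-Event list and the
drug-label list are licensed artefacts consumed as user-supplied CSVs; the
map is treated as authoritative and no reclassification is applied (FAERS's
own occasionally surprising placements, e.g. lip disorders under
gastrointestinal disorders, are preserved deliberately). PTs absent from the
map go to a sentinel SOC `"UNMAPPED"` and are counted. Flags: `is_ime` when
the PT is on the IME list, `is_unlabeled` when it is absent from the label
list.

**Ages** normalise to years through the unit code (decades ×10, months ÷12,
weeks ÷52.1775, days ÷365.25, hours ÷8766) and bin as `<18`, `18–65`,
`66–85`, `>85` with half-open lower bounds, so age exactly 18 falls in
`18–65` — the only reading under which the conventional bin labels are
mutually consistent.

## Disproportionality model

For each term at a MedDRA level (PT or SOC) a 2×2 table is built. The
counting unit is the **distinct (report, term) pair**: `a` target-drug
reports with the term, `b` remaining target-drug pairs, `c` other-drug
reports with the term, `d` the remainder, `N = a+b+c+d` the total number of
pairs. Under this convention the margins equal total term mentions, the
standard choice for spontaneous-report databases; a report-level mode
(`counting = "report"`, where `N` counts reports) is available because the
convention is not universal. Terms with `a = 0` carry no information about
the drug and are suppressed.

The four estimators:

- **ROR** `= ad/bc` with Wald interval
  `exp(log ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`. If any of `b`, `c`, `d`
  is zero all four cells get the Haldane–Anscombe +0.5, keeping the
  statistic finite without perturbing ordinary tables.
- **PRR** `= [a/(a+b)]/[c/(c+d)]` with Pearson's χ²
  `N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]`, no continuity correction by default
  (the Yates variant is a flag; published analyses rarely state which they
  used, and the uncorrected form is the common default).
- **BCPNN information component**, the closed-form posterior formulation:
  with `γ11 = 1`, `α1 = β1 = 1`, `α = β = 2` and the adaptive joint prior
  count `γ = γ11(N+α)(N+β)/[(a+b+α1)(a+c+β1)]`,

  `IC = log2[(a+γ11)(N+α)(N+β) / ((N+γ)(a+b+α1)(a+c+β1))]`,

  with the delta-method posterior variance `v` and `IC025 = IC − z√v`.
  `z = 1.96` by default; the classical `−2√v` variant is a parameter. As
  `N → ∞` at fixed proportions `IC → log2[aN/((a+b)(a+c))]`, verified to
  0.01 bits at `N = 10⁶` in the tests.
- **MGPS / EBGM.** The relative reporting rate `λ` of each table has the
  two-component gamma mixture prior
  `λ ~ p·Gamma(α₁, β₁) + (1−p)·Gamma(α₂, β₂)`; counts are
  `a | λ ~ Poisson(λE)` with `E = (a+b)(a+c)/N` the independence
  expectation (no stratification — the pipeline applies none by design).
  The marginal is a two-component negative-binomial mixture whose five
  hyperparameters are estimated by maximum likelihood over all tables at one
  level: Nelder–Mead then a BFGS polish on log/logit-transformed parameters
  from the canonical start `(0.2, 0.1, 2.0, 4.0, 1/3)`, with the log-scale
  parameters boxed in `±log(10⁶)` — small table sets otherwise drift to
  degenerate point-mass components. Fewer than 10 tables returns the
  canonical start flagged non-converged rather than a meaningless fit. The
  posterior is again a gamma mixture with components `(αⱼ+a, βⱼ+E)`;
  `EBGM = 2^{E[log2 λ | a]}` via digamma expectations and `EBGM05` is the
  5th posterior percentile by root-finding on the mixture CDF. Both match a
  numerical-integration oracle of the raw posterior density to 10⁻⁴, and on
  5,000 cells simulated from the canonical prior the hyperparameters are
  recovered within 25% relative error (both asserted in the acceptance
  suite).

**Significance criteria** (defaults): ROR — CI lower bound > 1 and `a ≥ 3`;
PRR — PRR ≥ 2, χ² ≥ 4, `a ≥ 3`; BCPNN — IC025 > 0; MGPS — EBGM ≥ 2. The
EBGM gate defaults to EBGM itself, matching the printed threshold convention
"EBGM ≥ 2"; gating on EBGM05 (the conservative reading, since signal tables
conventionally print EBGM05 in parentheses) is a configuration switch. A
**consensus signal** requires all four, which trades sensitivity for a very
low false-positive rate; no multiple-testing adjustment is applied beyond
the fixed per-term thresholds — a known limitation of the fixed-threshold
tradition this pipeline reproduces.

## Time to onset and summaries

Onset is `event date − earliest target-drug therapy start date`, in calendar
days. The event date comes from the DEMO record (the FAERS field for event
onset; reaction records carry no date), and the earliest start is used when
several therapy episodes exist because first exposure bounds onset.
Day-resolution arithmetic requires full 8-digit valid dates on both sides;
otherwise the case is excluded as `missing_date`, and negative differences
as `negative`. The accounting identity
`included + missing_date + negative = cases` is asserted as an invariant.
Median and quartiles use linear interpolation (the inclusive method, R type
7); day bins default to 0–30, 31–60, 61–90, 91–180, 181–360, >360 —
month-one, months 2–3 by month, months 4–6, 7–12, and beyond — and are fully
configurable. Demographic summaries report counts and percentages (one
decimal, denominator all cases) for sex, age group, reporter class, top-k
countries, outcomes (multi-valued: a case counts in every outcome it
reports) and top-k indications, plus reports per year keyed on the FDA
receipt year, for which partial dates still contribute.

## The synthetic generator

`simulate_faers()` emulates the structural features the pipeline must
survive: multi-table reports linked by PRIMARYID/CASEID, drugs with role
codes, several distinct PTs per report, duplicate case versions with later
FDA_DTs (ties at 10% to exercise the PRIMARYID tie-break), missing and
partial (YYYYMM / YYYY, 5%) dates, and occasional negative onset intervals
produced by swapping start and event dates — exercising the exclusion rule
without a second date model.

Events are drawn per (report, PT) as independent Bernoulli trials with
probability `min(1, p_event × multiplier)` when the report carries the
signal drug. This makes the designed multiplier the exact asymptotic
pair-level reporting odds ratio, which is the property the recovery tests
need; a count-first scheme (draw the number of events, then sample PTs by
weight) cannot deliver exact per-pair probabilities because the per-report
weight sum differs between arms. The default PT catalog's background
probabilities sum to ≈2, so the per-report event count is still ≈
1 + Poisson(1) in expectation. Reports that draw no event receive one PT
sampled proportionally to their inclusion probabilities (zero-probability
PTs are never forced), a <15% perturbation applied nearly equally to both
arms; empirically the designed multiplier is recovered within ~2% and its
95% CI coverage across seeds stays at or above the nominal rate asserted in
the tests.

The default study conditions mirror a plausible single-drug cohort: one
target drug used in 10% of reports, always primary suspect; five background
drugs with mixed roles; onset intervals log-normal with median 81 days and
quartiles near 31/169; demographic fields drawn at rates typical of a
dermatology cohort (56% female, 44% missing age, 81% US reports, outcomes
dominated by "other serious"). These are generator conditions, not
estimates: what passing tests show is that the pipeline recovers designed
effects under realistic data pathologies, not that any real drug behaves
this way. The generator deliberately omits pharmacological structure —
dose, drug–drug interactions, reporter/country covariance, secular trends —
so it cannot validate analyses that depend on those.

## Numerical and design choices

- Dates are validated as real calendar dates; an 8-digit string that fails
  round-trip parsing counts as a warning and becomes missing.
- The "$" dialect has no quoting; a field containing the delimiter is a
  write error rather than silent corruption.
- Deduplication compares PRIMARYIDs numerically when all parse as numbers
  (the FAERS case), lexically otherwise.
- The mixture-prior components are exchangeable; reported hyperparameters
  may be label-swapped relative to a reference, which affects nothing
  downstream.
- Problem sizes in the validation suite: oracle equivalence on 1,000-case
  datasets (exact, not approximate); signal recovery and specificity at
  50,000 cases × 20 seeds with a multiplier-10 pair at background
  probability 0.02; prior recovery from 5,000 simulated cells. These sizes
  put Monte-Carlo error well below the asserted tolerances while keeping the
  default check runnable in minutes on one CPU.

## Known limitations

Disproportionality measures reporting association, not causation or
incidence; the consensus rule inherits every reporting bias in the data.
LLT→PT recoding, active-ingredient spelling correction, stratified or
regression-adjusted estimators, and parametric onset models are out of
scope. The PT→SOC map assigns each PT a single SOC; MedDRA's
multi-axiality (a PT with secondary SOCs) is not modelled.
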