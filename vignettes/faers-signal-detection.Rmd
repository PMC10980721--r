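---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect unsolicited safety reports: a patient, a
set of suspected drugs with role codes (primary suspect, secondary suspect,
concomitant, interacting), a set of adverse events coded as MedDRA
Preferred Terms (PTs), dates, and outcomes. There is no denominator of
exposed patients, so "is this event reported unusually often with this
drug?" is answered by *disproportionality*: comparing the event's share of
the target drug's reports against its share of everybody else's reports.

pvsignal implements that workflow end to end for FAERS-style quarterly
ASCII data: ingestion, the FDA-recommended case deduplication, selection of
a target-drug primary-suspect cohort, descriptive constituent-ratio
summaries, 2×2 contingency tables per event at the PT and System Organ
Class (SOC) levels, and four disproportionality statistics with their
conventional signal thresholds. A synthetic corpus generator with injected
reporting-rate signals makes every stage testable without access to the
real database.

## Data model and deduplication

A *case* (CASEID) can appear as several report versions (PRIMARYID), and
the FDA receive date (FDA_DT) orders those versions. For each case exactly
one report is kept: the one with the largest FDA_DT, ties broken by the
largest PRIMARYID. The rationale is that the most recently received version
carries the most complete information. Quarterly packages also ship a
deleted-report list (one CASEID per line, distributed since 2019Q1); those
cases are removed after deduplication, and child-table rows
(DRUG/REAC/OUTC/THER) of removed reports are dropped in the same pass.

Two conventions the file format forces:

* **Dates.** Raw values may be full (`YYYYMMDD`), partial (`YYYYMM`,
  `YYYY`) or absent. We keep the raw digit string plus a parsed `Date` that
  is set only for valid full dates. Deduplication compares the *integer
  value* of the raw string, so partial dates still order deterministically
  and a missing FDA_DT sorts lowest — a dated version always beats an
  undated one. Anything that is not a 4/6/8-digit string becomes missing
  (with a count in the log), never a dropped row.
* **Dedup scope.** The kept set is computed globally over all loaded
  quarters, and the deleted list is the union over quarters.

## Cohort and descriptive summary

A report enters the cohort when at least one drug row has a role in the
configured set (default: primary suspect only) and `drugname` or `prod_ai`
contains the keyword as a case-insensitive substring — robust against the
casing and punctuation noise typical of verbatim drug names.

The descriptive summary reports counts and *constituent ratios*
(100·count/cohort size, rounded half-up to 2 decimals) by gender, age bin,
reporter type, country, report year, serious outcome and time to onset.
Conventions, each chosen because the alternative is ill-defined:

* **Age bins** are half-open — [0,18), [18,45), [45,65), [65,75),
  [75,∞) — so the bin edges 45/65/75 each belong to exactly one bin and
  the bins partition the non-negative reals. Ages are first converted to
  years (YR×1, DEC×10, MON÷12, WK÷52.1775, DY÷365.25, HR÷8766; a missing
  unit is treated as years with a warning).
* **Report year** is the year of the kept version's FDA receive date, the
  field the dedup rule keys on.
* **Serious outcomes** are counted per report with multiplicity across
  outcome codes (one report can be both a hospitalization and a death);
  the denominator stays the cohort size, so this dimension need not sum
  to 100%.
* **Time to onset** is the event date minus the *earliest* therapy start
  among therapy rows linked to matched drug rows, both full dates;
  partial/missing dates and negative differences are excluded (the
  excluded fraction is logged). Bins: 0–30, 31–60, 61–90, 91–120, 121–150,
  151–180, 181–360, >360 days.
* **Rounding** is half-up, matching how published constituent-ratio
  tables are printed. Note that a dimension with k rounded categories can
  drift from 100% by up to 0.005·k.

## Contingency tables

The counting unit is the **distinct (report, event) pair**: a report
listing the same PT twice counts once, and at SOC level a report counts
once per distinct SOC (PTs are mapped to their primary SOC through a
user-supplied TSV; MedDRA is licensed and not bundled; unmapped PTs go to
an explicit `UNMAPPED` bucket). For each event *e*,

|                | event *e* | other events | total |
|----------------|-----------|--------------|-------|
| target drug    | a         | b            | a+b   |
| all other drugs| c         | d            | c+d   |

with b and d computed from the *unit* margins (total cohort units − a,
total non-cohort units − c). Unit-based margins are the dominant FAERS
convention and make N identical across events at a level, which is what a
single-table layout requires. Events never reported with the target drug
are retained with a = 0 and flagged non-computable rather than dropped.

## The four statistics

With cells a, b, c, d and N = a+b+c+d:

* **ROR** = ad/bc with the log-scale Wald CI
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)). Signal: a ≥ 3 and lower CI
  bound > 1.
* **PRR** = [a/(a+b)]/[c/(c+d)] with
  SE(lnPRR) = √(1/a − 1/(a+b) + 1/c − 1/(c+d)); same threshold. The
  accompanying χ² is the Yates-corrected Pearson statistic
  N(|ad−bc| − N/2)²/((a+b)(c+d)(a+c)(b+d)), floored at 0 when
  |ad−bc| < N/2; an uncorrected variant is a config switch.
* **BCPNN**: the observed information component
  IC = log₂[aN/((a+b)(a+c))] plus its Bayesian shrinkage expectation
  E(IC) and variance V(IC) under Dirichlet/beta priors
  (γ₁₁ = α₁ = β₁ = 1, α = β = 2 by default, all exposed), with the
  derived weight γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁)). The decision bound
  IC025 = E(IC) − 2√V(IC) is a 2-standard-deviation bound, not a posterior
  quantile. Signal: IC025 > 0. Because the priors regularize, E(IC), V(IC)
  and IC025 stay defined even at a = 0.
* **EBGM** here is the closed-form relative reporting ratio
  aN/((a+c)(a+b)) with a log-scale Wald CI using the same SE term as the
  ROR. Signal: EBGM05 > 2. This is deliberately *not* a DuMouchel
  gamma-mixture posterior: no mixture fit is performed, and the point
  estimate satisfies IC = log₂(EBGM) exactly. Users needing the full
  empirical-Bayes machinery should reach for a dedicated MGPS
  implementation.

Numerical policy: no continuity corrections anywhere; any statistic whose
formula touches a zero cell is marked non-computable (`NA`) and can never
flag. Cells are coerced to double before arithmetic so products like
(a+b)(c+d)(a+c)(b+d) cannot overflow integer range. Internally everything
is kept at full precision; the 2-decimal formatting exists only in
`format_signal_table()`. The combined signal policy defaults to
"all four methods agree", with `"any"` available — consensus is the more
specific choice and the conventional one when four methods are run side by
side.

Ranking is a stable descending sort by case reports or by EBGM, ties
broken by case reports then alphabetically, so output order is fully
deterministic.

## The synthetic generator

`generate_corpus()` emulates the *structure* of a spontaneous-report
database, not its pharmacology:

* Drugs and PTs have power-law popularity weights (rank⁻¹ by default over
  50 drugs and 200 PTs). Each report gets exactly one primary-suspect drug
  and a geometric number (mean 1, cap 4) of secondary/concomitant drugs.
* Each PT enters a report as an **independent Bernoulli** with
  weight-proportional probability scaled to a configurable mean (~2 PTs
  per report). An injected signal (drug D, PT j, λ) multiplies the
  inclusion *odds* of j by λ for reports whose primary suspect is D. This
  mechanism is chosen because its true ROR equals λ asymptotically, giving
  recovery tests a closed-form truth; a report that draws zero PTs
  receives one background PT so every report has at least one reaction.
* Dates are generated causally (therapy start → onset delay → FDA receipt,
  with mostly short onset delays and a small long tail) and then degraded:
  configurable fractions become partial or missing.
* Duplicates clone a case with a later FDA date and a fresh primaryid and
  touch nothing else, so dedup correctness is exactly checkable; a
  configurable fraction of caseids lands on the deleted list. Defaults are
  10% duplicates and 2% deletions.
* Sex defaults to a female-majority mix (61% of known), ~7.6% unknown;
  reporter and country mixtures are consumer- and US-dominated — the
  shapes seen in real spontaneous data.
* The generator returns a `synthetic_truth` object: the injected specs
  with realized post-dedup counts, so tests can compare pipeline output
  against ground truth rather than against itself.

What the generator does **not** emulate: pharmacological co-reporting
structure (drug classes, indications, confounding by comorbidity),
free-text drug-name noise beyond casing/punctuation, reporting-rate trends
within a drug, or stratification effects. Passing recovery tests therefore
demonstrates that the pipeline's accounting and statistics are correct
under a known mechanism — not that the thresholds are well calibrated for
any particular real drug.

## Validation design and problem sizes

Three layers of checks back the implementation:

1. **Worked-example ratios** — the constituent-ratio computation is run on
   published numerator/denominator pairs of a 23,575-report cohort and
   must reproduce the printed two-decimal percentages exactly.
2. **Formula-oracle equivalence** — on 1,000 random all-positive tables
   the vectorized statistics must agree to 10⁻¹⁰ relative error with an
   independently coded scalar oracle (the χ² routed through
   `stats::chisq.test`), including a hand-derived fixture
   (6,4,3,8 → ROR 4.0, PRR 2.2, EBGM 1.4, γ = 529/110).
3. **Simulation properties** — (i) on 2,000 fixed-margin null tables with
   expected a ≥ 3 (hypergeometric a; the construction under which the
   Wald CIs are asymptotically valid), the ROR criterion's false-flag rate
   must stay below 2.5% plus three Monte-Carlo standard errors; (ii) over
   20 seeded corpora of 6,000 reports with pairs injected at λ = 10/15/20
   on a moderately popular drug (expected a ≈ 20–40), the all-four-method
   policy must flag ≥ 90% of injected pairs, and deduplication must
   recover exactly the distinct-surviving-case count under 10% duplicates
   and 2% deletions.

These corpus sizes keep the whole validation run within a couple of
minutes while leaving the expected counts an order of magnitude above the
decision thresholds' boundary region.

## Known limitations

* The EBGM column is a closed form, not an MGPS posterior; for rare events
  it shrinks less than a fitted empirical-Bayes estimate would.
* No stratification (age/sex/year) and no multiple-testing adjustment are
  applied — standard for first-pass disproportionality screens, but both
  matter for formal inference.
* Country and reporter codes pass through verbatim; harmonization
  ("US" vs "United States") belongs to the input preparation.
* Fuzzy duplicate detection (same patient under different caseids) is out
  of scope; only the CASEID-based rule is implemented.
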