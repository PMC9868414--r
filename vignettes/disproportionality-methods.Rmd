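---
title: "Methods: disproportionality screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrscreen)
```

## The problem and the model

Spontaneous-reporting databases such as FAERS accumulate voluntary case
reports: a patient, the drugs they took, and the adverse events observed,
coded as MedDRA Preferred Terms (PTs). Reporting is uncontrolled — there
is no denominator of exposed patients — so absolute risks cannot be
estimated. Disproportionality analysis instead asks whether a drug-event
pair is reported *out of proportion*: for each pair, the deduplicated
database is collapsed to a 2×2 table with cells `a` (drug and event), `b`
(drug, no event), `c` (event, no drug) and `d` (neither), where the
background is every report not mentioning the drug. The proportional
reporting ratio

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$$

compares the event's reporting frequency among the drug's reports with
its frequency in the background, and the chi-squared statistic of the
table measures the support. A pair is flagged as a positive signal by the
Evans criterion — `N = a ≥ 3`, `PRR ≥ 2` and `χ² ≥ 4`, all boundaries
inclusive — a deliberately simple rule that trades formal error control
for transparency and has been the workhorse of PRR-based screening for
two decades.

Assumptions worth keeping in view: each deduplicated report is treated as
an independent case; drug membership is report-level (a report either
mentions the drug or not, however many times); the background is the whole
remaining database, so signals are relative to everything else reported,
not to a therapeutic comparator; and no adjustment is made for
confounding (e.g. by indication) or for testing hundreds of pairs at
once. Signals are reporting associations, never causal estimates.

## Pipeline stages and their contracts

1. **Reading** (`read_report_tables`): the three-table layout (demographics,
   drug mentions, reaction PTs) is validated strictly — missing columns,
   orphan rows and reports without a single drug mention are errors, since
   each silently dropped row would bias a cell of every downstream table.
2. **Deduplication** (`deduplicate`): a case may be submitted repeatedly as
   versioned reports; one record per `case_id` is kept — the highest
   version, ties broken by the lexicographically greatest `report_id`.
   The tie-break makes the operation a pure function of the data.
   Duplicate (case, version) pairs are tolerated on input because real
   extracts contain them.
3. **Name mapping** (`load_vocabulary`, `map_drug_name`): verbatim drug
   strings are mapped to canonical drugnames by exact lookup after
   case-folding and whitespace collapsing. There is deliberately no fuzzy
   or substring matching: a dictionary-style exact match is predictable
   and auditable, whereas edit-distance matching silently inflates `a`
   cells. Unmapped names stay unmapped. Fixed-dose combinations (e.g.
   losartan + hydrochlorothiazide preparations) are canonical names in
   their own right, distinct from their components, because combination
   products are reported — and screened — as entities.
4. **Event definitions** (`event_definition`): an adverse event of
   interest is a non-empty PT set; a report carries the event if any of
   its PTs is in the set (case-insensitive). A composite event over
   several PTs is exactly the OR of the single-PT events.
5. **Screening** (`run_screen`): the full vocabulary × event cross is
   screened; pairs whose statistics are undefined (drug never reported,
   event absent from the database, event in every report, or no
   background) are retained with a reason code and a negative
   classification rather than dropped.

## Tunable parameters

| parameter | default | meaning |
|-----------|---------|---------|
| `yates` (`run_screen`, `compute_chi2`) | `TRUE` | Yates continuity correction. The signal criterion's chi-squared threshold is conventionally applied to the corrected statistic, and the correction is what OpenVigil-style front-ends compute; the plain Pearson form is available because other published screens use it. The corrected statistic is never larger, so `yates = TRUE` is the conservative choice. |
| `continuity` (`compute_prr`) | `0` | Haldane-style constant added to all cells. With 0, a drug-only event gives `PRR = Inf`; that is safe under the Evans rule because the case-count and chi-squared arms still gate the classification, and it faithfully reports "never seen in the background". `0.5` yields finite ratios when a shrunk estimate is preferred. |
| age bins (`summarize_event`) | `[0,18), [18,41), [41,66), [66,∞)` | Integer-year bins behind the conventional "0–17 / 18–40 / 41–65 / >65" labels, so a 65-year-old falls in 41–65 and an 18th birthday moves a patient to 18–40. Ages are converted to years at read time (months/12, days/365.25). |
| rounding | half-up, 2 decimals | Printed percentages and statistics use commercial rounding (`round_half_up`), matching how published signal tables are typeset; base R's round-half-even would disagree on exact halves. |

## The synthetic-data generator

`generate_reports` draws a FAERS-like database with known ground truth.
Per report: drug mentions are independent Bernoulli draws per canonical
drug (all-zero rows are resampled so every report has a drug, keeping the
remaining marginals interpretable, at the cost of a slight truncation
bias discussed below); each PT is then drawn with probability
`background_event_prob × m`, where `m` is the largest planted `lambda`
among the report's drugs for that PT and 1 if none, capped at 1; sex, age
and country are drawn from configurable distributions with explicit
"unknown" mass; and each mention is rendered as the canonical name or,
with probability `synonym_noise`, a synonym or case variant, exercising
the name-mapping path. An optional `duplicate_case_prob` emits version-1
duplicates so deduplication is exercised end to end. Everything is
deterministic given the config, whose seed is applied with
`withr::local_seed` so user RNG state is untouched.

`expected_prr` gives the closed-form PRR implied by a config: the ratio
of the event probability conditional on the drug's presence to that
conditional on its absence, enumerating the presence patterns of the
other planted drugs. For a single planted pair with independent drugs it
is exactly `lambda`; for unplanted drugs it is exactly 1. Two
approximations separate it from the generator: the at-least-one-drug
resampling (which inflates presence probabilities by a common factor and
couples drugs weakly — an O(marginal) effect) and the cap of the event
probability at 1 (exactly accounted for in the enumeration). Validation
therefore compares estimates with `expected_prr` on the log scale within
Wald sampling intervals rather than expecting exact agreement.

What the generator does *not* emulate: co-prescription correlation
(mentions are independent per drug unless planted on the same PT),
reporting-volume trends over time, stimulated reporting after safety
communications, indication-driven channeling, and real FAERS's messy
verbatim text beyond synonym/case noise. Passing the validation suite
shows the pipeline's arithmetic and plumbing are right under the stated
sampling model — not that real-data signals are unconfounded.

## Reference-table regressions

The printed signal tables of a published antihypertensive screen (one row
per positive (drug, event) signal with N, PRR and χ²) ship as transcribed
CSV fixtures. The underlying 2×2 tables would require the full
multi-million-report FAERS extract, which is out of scope; but everything
downstream of the printed numbers is recomputed: re-applying the Evans
rule classifies every printed row positive and reproduces the per-event
positive-signal counts (46, 64, 27, 8, 6 across the five urate-related
events), the cross-event overlap histogram (42 drugs positive for more
than one event: 19 with exactly two, 15 with exactly three, 6 with four,
2 with all five), and all 55 report-overview percentages from their
printed counts. Two transcription notes: the gout signal table prints 64
rows where the source's running text counts 66 drugs (the fixtures keep
the printed rows, and no test asserts a gout row count); and the gout
reporter-country counts sum to 120 more than the gout report total while
their percentages are taken against the total — the fixture transcribes
the counts as printed and the consistency test asserts that discrepancy
explicitly rather than "repairing" it.

## Numerical and degenerate-input choices

- `PRR`: `a = 0` returns 0; `c = 0` with `a > 0` returns `Inf`; an empty
  drug row (`a + b = 0`) or empty background (`c + d = 0`) is an error at
  the single-pair level and a reason-coded negative in a batch screen.
- `χ²`: any zero marginal is an error (the statistic is undefined); the
  Yates form floors at 0 when `|ad − bc| ≤ n/2`.
- `classify_signal` treats `NA` statistics as negative (no evidence, no
  signal) and `Inf` PRR as satisfying the PRR arm.
- Class display order in grouped tables comes from the vocabulary file's
  `class_order` (diuretics first, compound preparations last, as is
  conventional); within a class, vocabulary entry order. Ordering is thus
  data-independent and stable across runs.
- Screens are invariant to report order and drug-mention order; mapping
  is invariant to vocabulary entry order because synonym collisions are
  rejected at load time.

## Validation problem sizes

The test suite exercises the statistics against independent oracles
(cell-wise Σ(O−E)²/E and `stats::chisq.test`) on 1000+ random tables,
checks contingency construction against a brute-force per-report recount
on 200-report random databases, and runs parameter recovery on a
50,000-report synthetic database with background event probability 0.002
and a planted multiplier of 5 — sizes at which a planted pair yields a
few dozen cases, comfortably above the criterion's thresholds, while the
whole suite runs in well under a minute. The null-calibration check
screens 100 unplanted pairs and expects the flagged share well below
10%: the chi-squared arm alone bounds the per-pair null rate near 5%,
and the joint criterion is stricter.

## Known limitations

- No multiplicity control across the screened pairs, mirroring standard
  PRR screening practice; with hundreds of pairs, a few percent of null
  pairs will be flagged by chance, which is why signal counts — not
  individual signals — are the primary regression quantities.
- Report-level drug counting cannot distinguish suspect from concomitant
  drugs (FAERS role codes are not modelled).
- The background is the full remaining database; restricted backgrounds
  (e.g. same-class comparators) are not implemented.
- Exact-match name mapping means misspellings count as unmapped rather
  than being rescued; that is a feature for auditability but understates
  exposure in dirty data.
- MedDRA hierarchy traversal (LLT/HLT/SOC) is out of scope: event
  definitions are explicit PT sets supplied by the user.
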