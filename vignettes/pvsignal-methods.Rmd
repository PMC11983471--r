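---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-reporting databases such as FAERS collect adverse-event reports
from physicians, pharmacists, manufacturers, consumers and lawyers. They are
the main instrument of post-marketing drug surveillance, and they are messy:
the same clinical case is resubmitted under new report versions, drug names
arrive as free text, and reporting is voluntary and biased. `pvsignal`
implements the standard analysis chain for asking "which drugs are
disproportionately reported with event X?" against this kind of data, with
kidney stones (MedDRA preferred term *nephrolithiasis*, code 10029148) as
the default target event.

The chain is: read the quarterly ASCII tables → collapse duplicate case
submissions → extract the case set for the target preferred term →
normalize verbatim drug names to generics → build per-drug 2×2 tables
against the deduplicated background → compute reporting odds ratios, flag
signals, and cross them against drug-label information → stratify the case
set demographically.

## The model

For each drug *X* and the target event *E*, reports are cross-classified:

|            | event *E* | other events |
|------------|-----------|--------------|
| drug *X*   | a         | b            |
| other drugs| c         | d            |

The reporting odds ratio is ROR = (a·d)/(b·c), with the Woolf (log-normal)
interval

ROR~95~ = exp( ln ROR ± 1.96 · √(1/a + 1/b + 1/c + 1/d) ).

A drug is flagged as a **signal** when a ≥ 3 and the lower 95% bound exceeds
1. The point estimate is the geometric mean of its CI bounds — an identity
the test suite asserts to 1e-9, and which also lets published (ROR, CI)
triples be checked for internal consistency without access to the raw
counts. The ROR is a measure of *reporting* disproportionality, not of
risk: it inherits every reporting bias in the database, and a signal is a
hypothesis, not a causal claim.

Signal-positive drugs are then split into *known-risk* (the event appears
on the product label, per a user-supplied label-risk list) and
*potential-new-signal* — the label-gap output that motivates this kind of
study.

### Choices inside the estimator

* z is fixed at 1.96 (nominal 95% two-sided). No multiple-testing
  adjustment is applied across drugs; the signal rule is the conventional
  per-drug criterion.
* Tables with a zero cell have an undefined estimate and can never be
  signals, unless the optional Haldane–Anscombe correction
  (`continuity = "on"`) is chosen, which adds 0.5 to all four cells of the
  affected tables and flags the result `corrected`. The correction is off
  by default because the signal rule already requires a ≥ 3.
* The unit of counting is the *report*: a drug mentioned on three rows of
  one report, or an event coded twice, counts once. This is enforced
  upstream (mention collapsing) and is what makes the marginals of every
  2×2 table sum to the deduplicated background count.
* All drug role codes (suspect, concomitant, interacting) count as exposure
  by default; `roles = c("PS", "SS")` restricts to suspects. The permissive
  default matches an extraction that keeps all drug records; restricting to
  suspects is the usual sensitivity analysis.
* Ranking for the "top N" table is by a (report frequency), ties broken
  alphabetically so output is deterministic.

## Deduplication

Case submissions are collapsed with the FDA-recommended key rule: group by
CASEID, keep the report with the most recent FDA_DT, break receipt-date
ties by the largest PRIMARYID. Details that the rule itself leaves open and
that this package fixes explicitly:

* primaryids are compared as zero-padded strings, which equals numeric
  order for the all-digit ids FAERS uses (avoids "9" > "10").
* Records whose FDA_DT is missing or partial (YYYY or YYYYMM) keep their
  raw value but rank *below* any fully dated record, so a dated
  resubmission always supersedes an undated one. This is a declared,
  conservative convention — sources describing the rule do not say how
  undated reports were handled.
* Records with an empty CASEID cannot be grouped; they are quarantined and
  reported, never merged.
* Deduplication is global across all loaded quarters, matching a pooled
  multi-year analysis rather than per-quarter cleaning.

The contract is covered by algebraic tests (idempotence, conservation,
permutation invariance) and by brute-force per-case argmax oracles on
random fixtures.

## Drug-name normalization

Name standardization tools (e.g. MedEx) are effective but not reproducible
offline; this package instead makes the mapping an explicit, auditable
input: a CSV of `verbatim → generic (+ ATC)`. Keys are lowercased,
whitespace-collapsed, and trailing dosage/form tokens are stripped
("HUMIRA 40MG" → "humira"). Misses pass through as the normalized string
with `matched = FALSE` — mentions are never dropped silently, and the match
rate is reported per run. Combination products (generic fields containing
`+`) expand to their component generics, flagged `combination`. A starter
dictionary for a few dozen well-known generics ships with the package; the
packaged label-risk list is likewise an illustrative synthetic starter.
Top-N membership is dictionary-dependent by construction, so real analyses
should supply curated tables.

## Descriptive stratifications

Age bands are ≤17, 18–65, 66–85, ≥86 and unknown; ages arrive with unit
codes (years, months, decades, days...) and are converted to years first.
Percentages are **rounded half-up to two decimals**, and the denominator is
always the *total* case count including unknowns — the only convention
under which a published table of stratum counts and percentages is
internally consistent (e.g. 16,219 of 38,307 → 42.34%). Half-up matters:
banker's rounding would turn 0.695 into 0.69. Single-valued dimensions
(age, sex, reporter, country, year) partition the case set; the outcome
dimension counts case–outcome pairs and may exceed 100%.

## The synthetic generator

Real FAERS extracts are hundreds of millions of rows across 80+ quarters;
every stage here is instead validated against a generator that emits
FAERS-format files with known ground truth.

Per report, exposures are drawn independently per drug (probability
`p_drug`); with baseline event probability q, a report exposed to drug j
has event probability q·ρ~j~/(1 − q + q·ρ~j~), which makes the
report-level odds ratio of event against exposure exactly ρ~j~.
Multi-exposure reports use the maximal implied probability — a documented
simplification under which per-drug marginal odds ratios stay ≈ ρ~j~ while
exposure probabilities are small (they are ≤ 0.035 in the defaults).
Duplicate submissions are injected at rate `dup_rate`: a copied report with
the same CASEID, FDA_DT bumped 1–90 days, and a fresh larger PRIMARYID —
exactly the configuration the keep-latest rule must resolve. The manifest
records every truth: case ids, per-drug realized 2×2 counts, demographic
values, and duplicate lineage.

Default conditions (chosen once, as a plausible kidney-stone-like mix):

* q = 0.0182, the case fraction implied by ≈38,300 cases in ≈2.1 million
  reports.
* Planted ρ for the named signal drugs mirror published signal strengths
  (atazanavir 33.29, topiramate 8.35, lansoprazole 7.20, teduglutide 5.54);
  the frequently reported biologics get moderate ρ of 1.8–2.3; metformin
  and lisinopril are null (ρ = 1).
* Demographics use the published marginal shares where stated, with unknown
  shares as remainders (sex unknown = 100 − 53.16 − 39.46 = 7.38%, since
  the printed "unspecified" share is inconsistent with the named shares).
* `dup_rate = 0.08`, a realistic resubmission share; no published figure
  exists for it.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: reporting-bias dynamics (Weber effect, stimulated
reporting), correlated co-prescription, indication confounding (the
biologic/IBD problem), country- or year-varying case mix, and free-text
noise beyond simple dosage suffixes and brand synonyms.

## Validation scale and stochastic checks

The statistical acceptance checks run 200 seeded replicates of
200,000-report universes with ρ ∈ {1, 2, 8} (coverage of the planted value
by the 95% CI must lie in 95% ± 4%) and 200 all-null universes (fraction
of drugs flagged ≤ 5%; the observed rate is ≈2.5%, as expected for a
one-sided exceedance at the 2.5% tail plus the a ≥ 3 gate). These sizes
give binomial standard errors of ≈1.5 percentage points on the coverage
estimate — small enough that the ±4 band is a ≈2.6σ test — while staying
cheap: one replicate costs about a second. Deterministic oracles (the
log-space ROR evaluation, a weighted-GLM Wald route, brute-force
contingency counting and per-case dedup argmax) run on fixtures of
10^2–10^4 records.

## Degenerate inputs and tie-breaks, collected

* Header-only table files → empty streams, zero malformed lines.
* Lines with the wrong field count → skipped and counted;
  `rows + malformed = data lines` always.
* Absent optional tables → empty streams with warnings; absent DEMO →
  error (nothing downstream is meaningful without the dedup key triple).
* Empty case set → empty strata and trend tables, not errors.
* Negative ages → "unknown" with a warning.
* Zero-cell 2×2 tables → undefined estimate unless corrected.
* Ranking ties → alphabetical; dedup ties → larger primaryid.

## Known limitations

Disproportionality is hypothesis-generating only. The package deliberately
implements a single method (ROR) — PRR, IC/BCPNN and EBGM/MGPS are not
included. There is no MedDRA hierarchy traversal (single-PT targets only),
no probabilistic record linkage across distinct CASEIDs, and no downloader
for FDA servers. The starter dictionary and label-risk list are synthetic
illustrations, not curated references.
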