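---
title: "Mining medication-use patterns from inpatient administration records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining medication-use patterns from inpatient administration records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medminer)
```

## The problem and the data model

One row of an inpatient medication-administration table documents a single
act of giving a drug: hospitalization episode, patient sex and birth date,
admission and discharge dates, medication name, route, dose quantity and
unit, and the administration date. `medminer` mines such tables for
recurring medication-use patterns in a paediatric inpatient setting, where
practice differs strongly by age.

Three modelling commitments shape everything downstream:

* **The mining unit is the hospitalization episode, not the patient.**
  A re-admitted child contributes one entry per stay; co-prescription and
  sequencing are facts about a single course of treatment.
* **Time is the calendar day.** Administrations on the same day form one
  *element*; intra-day ordering is not modelled. This matches how order
  sheets are written and keeps same-day combination therapy (e.g. several
  inhaled drugs nebulized together) distinct from day-to-day sequencing.
* **Age strata are half-open calendar intervals.** The six groups
  0–3 m, 3–6 m, 6–12 m, 1–2 y, 2–5 y and >5 y are assigned by
  calendar-month arithmetic on the admission and birth dates: a child
  exactly 3 months old on admission is in 3–6 m, one day younger in 0–3 m.
  Half-open intervals make the strata a true partition — a property the
  test suite checks on randomized date pairs.

## Cleaning

Two preparation steps precede any mining, both driven by a medication
catalog (JSON): raw route labels are merged to canonical ones
(`"IV drip"`, `"IV push"` → `"IV"`), and *diluents* — carrier solutions
such as dextrose 5% in water or normal saline, logged alongside almost
every IV administration but therapeutically inert — are removed, because
they would otherwise dominate every frequency ranking. The catalog also
canonicalizes shorthand names (`"D5W"`) to reference names. Cleaning is
conservative about data quality: rows that violate the record invariants
(administration outside the stay, negative dose, unparseable date) are
collected with their line numbers rather than silently dropped, and the
identity *raw records = kept + diluents removed + row errors* is asserted
in the tests. Medications missing from the catalog pass through with a
warning and a neutral utility weight `P = 1` by default (a strict
rejecting policy is available), so utility degrades gracefully to dose
mass rather than failing the run.

## The three database forms and miners

**Transactions / FP-Growth.** Each episode becomes its set of distinct
medications. `mine_frequent_itemsets()` builds a frequent-pattern tree
(items ordered by descending global support with lexicographic
tie-breaks, a header table linking equal items) and mines conditional
trees recursively. `min_support` is *relative* — a fraction of the
stratum's episode count, thresholded with a ceiling — because stratum
sizes differ by an order of magnitude; the default 0.15 is the
conventional operating point for this kind of co-prescription screen.
The implementation is exact: the suite checks it against an exhaustive
subset enumerator on hundreds of random databases, along with downward
closure and order invariance.

**Sequences / PrefixSpan.** Each episode becomes its day-ordered list of
elements. `mine_sequential_patterns()` grows patterns depth-first with
two move types: *item extension* (add a later-sorting item to the last
element — same day) and *sequence extension* (append a new element — a
later day). For every supporting sequence the projection keeps the
earliest element index at which the current prefix (and the prefix minus
its last element) can end; greedy-earliest matching is exact for
subsequence existence, and those two indices are exactly what is needed
to count both extension types. `max_length` (default 8 items; 3–4 in the
large end-to-end runs) bounds the output size, which otherwise grows
combinatorially on dense data. Patterns are canonically rendered
(`<(A, B), D>`, items sorted within elements) so equal patterns
deduplicate regardless of discovery path. Day gaps are *not* a mining
constraint — the mined order is purely relative — but
`mean_time_gap()` reports, post hoc, the mean calendar-day spacing of a
two-element pattern using earliest embeddings, the deterministic reading
of "A followed by B".

**Utility sequences / USpan.** Elements additionally carry the medication
utility *U(i, q) = P(i) × q*, with *q* the summed same-day dose.
Same-day repeat doses are aggregated into one item per (day, medication):
the day's total dose is what carries clinical meaning, and it keeps one
item per element per medication, which the sequence model requires.
`P(i)` is configuration, not data: it encodes how much one dose unit of a
medication "counts" (price, potency, expert weight — whatever the
analysis intends), and defaults to 1. A pattern's utility in a sequence
is the *maximum over embeddings* of the embedded items' summed utility —
the standard convention for utility-based sequence mining — and the
database utility sums these maxima over supporting sequences. Because
utility is not anti-monotone, `mine_high_utility_sequences()` prunes with
two provably safe bounds: items whose sequence-weighted utility (total
utility of the sequences containing them) cannot reach the threshold are
removed up front and candidate extensions are screened the same way
(width pruning), and a subtree is abandoned when best-embedding-plus-
remaining-utility falls below the threshold (depth pruning). Safety is
not taken on faith: the oracle tests compare the pruned search against a
brute-force enumerator with exhaustive embedding search, pattern for
pattern and score for score.

`min_utility` is absolute, as is conventional; a relative form
(`min_utility_rel`, a fraction of the database's total utility mass) is
provided because absolute thresholds do not transfer across datasets of
different scale. The end-to-end runs use `min_utility_rel = 0.05` — five
percent of a stratum's utility mass — chosen a priori as a level that a
genuinely dose-heavy regimen clears easily while the diffuse background
does not.

## Reporting

`top_k_patterns()` ranks by score (support or utility) with documented,
deterministic tie-breaks: score, then support count, then the canonical
rendering. `build_comparison()` aligns the top-k cells of the three
algorithms per age group into one table of distinct medication
*combinations*: itemsets are identified by their item set, sequences by
their canonical rendering, and a sequence matches an itemset when its
flattened set of distinct items equals the itemset — the natural rule for
"the same combination found by different views", made explicit here
because checkmark tables of this kind rarely state one. Empty cells (an
algorithm found nothing for a stratum) are simply absent rows.
`route_share()` and `frequency_table()` provide the record-level
treatment-pattern summaries (share of administrations by route class,
per-stratum medication frequencies, top-n coverage).

`fleiss_kappa()` implements the standard fixed-rater chance-corrected
agreement statistic for expert review of mined patterns: subjects ×
category counts in, `κ = (P̄ − P̄ₑ)/(1 − P̄ₑ)` out, with explicit errors
for degenerate tables (all ratings in one category). It is validated
against a hand-computed table to 1e-9, equals 1 under perfect agreement,
and is near 0 on large independently-random tables.

## The synthetic cohort

Real administration tables of this kind are not publicly shareable, so the
package ships a generator whose defaults emulate a large paediatric
pneumonia cohort: six age strata with weights (0.375, 0.080, 0.102,
0.109, 0.200, 0.135) — 86.6% under five; 60.1% of stays lasting 9–15 days
(the rest spread over 2–8 and 16–30 days with decaying weights); 60.4%
male; a 650-medication background catalog with Zipf(1.17) frequency
weights, calibrated so the top 40 medications cover roughly 74% of
records; routes assigned per medication, IV-heavy; and diluent records
attached to IV administrations with probability 0.9, then removed again
by cleaning — so the cleaning path does real work on every run.

Into this background the generator plants ground truth with disjoint
medication names (so mined support counts must *equal* the truth ledger's
realized counts, which the tests assert exactly):

* two same-day co-occurrence itemsets at prevalences 0.30 and 0.25;
* two two-step sequences at prevalences 0.30 and 0.25, with geometric
  day gaps of mean 7 and 5 days, censored at discharge (so realized mean
  gaps sit somewhat below the nominal means);
* one rare high-dose pair at prevalence 0.05 with a 25× dose multiplier —
  invisible to both frequency miners at support 0.15, found by USpan.

The planted prevalences were fixed once, by a binomial margin argument:
at 2,000 episodes even the smallest stratum (~160 episodes) keeps a
≥ 0.25-prevalence pattern above the 0.15 support threshold with several
standard deviations to spare. Generation is fully deterministic given the
config seed (identical seeds give byte-identical CSVs) and leaves the
caller's RNG state untouched.

What the generator does *not* emulate matters for interpretation: there
is no comorbidity, no dose-unit heterogeneity, no correlation between
background medications beyond shared marginal frequencies, and no
age-specific prescribing differences apart from the planted structure
being present in every stratum. Passing tests therefore demonstrate that
the pipeline recovers known structure under realistic marginals — not
that any particular clinical pattern exists in real data.

## Numerical and scale choices

* Support thresholds use `ceiling(min_support × n)`; a pattern at exactly
  the threshold is kept.
* Ties everywhere break deterministically (score, support count,
  lexicographic rendering), so outputs are reproducible across platforms
  and input orderings.
* Utility comparisons in tests allow ordinary floating tolerance; the
  miners themselves compare against thresholds with plain `>=`.
* Degenerate inputs are explicit: empty databases warn and return empty
  results; invalid thresholds, negative doses and malformed rating tables
  raise errors.
* Problem sizes: the oracle-equivalence suites run 200 random databases
  per miner at small sizes (≤ 8 items / ≤ 10 transactions for itemsets;
  ≤ 4 items, ≤ 6 sequences, ≤ 4 elements for sequences; utilities ≤ 20);
  the end-to-end runs use 2,000 episodes with per-stratum mining at
  `max_length` 4 (PrefixSpan) and 3 (USpan). These sizes were chosen so
  the full validation cycle completes in minutes on one core while still
  exercising every stratum.

## Known limitations

* USpan's exhaustive-with-pruning search can still blow up on dense
  databases with low thresholds; `max_length` is the practical guard.
* `P(i)` values are configuration; no canonical pharmacological weighting
  ships with the package.
* No dose-unit conversion or defined-daily-dose normalization is applied;
  utilities are only comparable within a medication.
* Gap statistics use earliest embeddings; other conventions (latest,
  all-embedding averages) would give different numbers on repetitive
  sequences.
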