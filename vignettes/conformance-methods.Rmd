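---
title: "Methods: conformance scoring and star rating of TCM outpatient records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformance scoring and star rating of TCM outpatient records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrqc)
```

## The assessment problem

Outpatient records from TCM hospitals are semi-structured: alongside the
usual demographics they carry four-diagnosis findings, symptom and
syndrome-type terms, and treatment entries, each with a terminology code.
When such records are exchanged between institutions, two defects dominate:
mandatory items left blank, and codes that belong to no recognised value
set. `emrqc` treats both as conformance-testing problems against a
declarative rule configuration, so that the same engine can serve any
concrete profile of mandatory items and code ranges.

A record is modelled as a fixed set of typed fields (scalars, multi-valued
lists, and a map of administrative codes). Normalization is applied at
ingest: surrounding whitespace is stripped everywhere; absent, empty and
whitespace-only values are all canonically *missing*; blank entries are
dropped from lists, so an all-blank list is a missing item. This
deliberately widens "cannot be blank" to cover the whitespace artifacts
common in real EMR exports. Codes are *not* case-folded: code-system
identifiers are case-defined, and case-insensitive matching would silently
accept near-miss codes.

## Scores

With $n$ records, $k_I$ mandatory rules and $k_C$ coding rules,

$$S_i = \left(1 - \frac{\sum_{i=1}^{n} X_i}{n \, k_I}\right)\cdot 100,
\qquad
S_c = \left(1 - \frac{\sum_{i=1}^{n} Y_i}{n \, k_C}\right)\cdot 100,
\qquad
S_t = w_1 S_i + w_2 S_c,$$

where $X_i$ counts record $i$'s missing mandatory items and $Y_i$ its
noncompliant coding items. Defaults: $k_I = 16$, $k_C = 13$,
$w_1 = w_2 = 0.5$. All three scores live in $[0, 100]$; they are held at
full double precision internally and rounded half-up to whole points only
for display (`display_score(80.5)` is `81`; base R's banker's rounding
would print 80). An empty batch is an error, never a vacuous 100 — the
formulas divide by $n$.

Two semantic decisions needed fixing where a plain "number of missing
items" cannot distinguish the failure modes of coded items:

* **Noncompliance ($Y_i$).** A coding item fails when any supplied code is
  outside its bound code range. For *strict* items — those that are also
  mandatory (gender code, dominant-disease code, and the four TCM
  terminology items) — a missing code also fails. Purely administrative
  value-set items (ethnicity, insurance type, severity, ID type, diagnosis
  type, payment method, nationality) are *checked-if-present*: they are not
  mandatory items, and counting their absence would double-penalize records
  for items the completeness profile never requires. The behaviour is a
  per-rule `strict` flag, so stricter local profiles are one configuration
  edit away.
* **Items appearing in both assessments.** Presence of a code list (e.g.
  "at least one symptom code") is an integrity question; validity of its
  members is a coding question. The two are assessed by separate rules and
  counted in their respective denominators.

The four TCM terminology rules need a field binding that the published
value-set tables leave open. The defaults bind therapeutic-method codes to
the treatment code list, syndrome codes to the syndrome-type code list,
clinic-terminology disease codes to the symptom code list, and the
diseases-and-Zheng classification to the dominant-disease code list (in
addition to that item's administrative value-set rule). These bindings are
ordinary configuration; a deployment whose records carry different coded
fields replaces them in the rules file.

## Star rating

Each record is graded against an ordered list of standards, every standard
a conjunction of named rule flags. With cumulative thresholds
$T = (5, 7, 9, 11, 14)$, the star level is the largest $L$ such that
standards $1 \dots T_L$ all hold; failing the 1-star prefix gives 0 stars.
Satisfaction beyond a broken prefix never counts: a false standard 3 forces
0 stars even if standards 4–14 are all true. This makes the level monotone
in every flag and equivalent to an exhaustive prefix search, which the test
suite verifies against a brute-force oracle (exhaustively over all $2^5$
flag vectors for a degenerate 5-standard scheme, and on 1,000 random
14-flag vectors).

The default 14 standards are derived from the default rules — 1–5: name,
ID number, age, gender code, location present; 6–7: pathological nature,
four-diagnosis findings; 8–9: symptom present, symptom code present and
valid; 10–11: TCM diagnosis, syndrome type with valid code; 12–14:
treatment, valid treatment code, valid dominant-disease code. The
item-to-standard map is a design choice of this package (the cumulative
5/7/9/11/14 structure is the fixed part); the scheme is serialized inside
the rule configuration and can be replaced wholesale.

**Batch star.** The published description of the batch-level aggregate is
incomplete, so the package uses the simplest aggregate composed of all
per-level counts: the count-weighted mean star level rounded half-up. It
is labelled a reconstruction in every report and is always accompanied by
the full distribution, so no information is lost if a deployment prefers,
say, a minimum-quota rule.

## Tunable parameters

| Parameter | Default | Meaning |
| --- | --- | --- |
| `weights` | (0.5, 0.5) | Integrity/coding mix in $S_t$; must sum to 1 |
| `strict` (per coding rule) | item-dependent | Missing code counts as noncompliant |
| mapping `delimiter` | `"\|"` | Separator of multi-valued cells in flat files |
| scheme `thresholds` | 5/7/9/11/14 | Cumulative prefix lengths per star level |
| `missingness` (generator) | 0.15 | Blanking rate for star-free mandatory items |
| `invalid_code_rate` (generator) | 0.10 | Out-of-range rate for star-free coded items |

## The synthetic generator

Real conformance data cannot be redistributed, so `generate_batch()`
produces batches with exact, construction-time ground truth. Each record
starts fully conformant (fixture vocabularies; codes drawn from the
intersection of every code set bound to the field — if that intersection
is empty the target is unreachable and generation errors rather than
guessing). For a target below the top level, the standard just past the
target's prefix is deliberately violated by blanking or invalidating one
of its referenced items. Items outside the pinned prefix and the violation
point are then corrupted independently: mandatory items blanked with
probability `missingness`, present coded items given an out-of-range code
with probability `invalid_code_rate`. The expected flags are tracked
through construction, not obtained by running the assessor, so the
generate→assess round trip is a genuine end-to-end check; the generator
verifies the intended star level from its own flags and raises an error on
schemes whose standards overlap in ways that make a target unreachable.

The default corruption rates (0.15 / 0.10) were chosen once as a
mid-range export quality a data-quality auditor would recognise; they are
deliberately not calibrated to any particular hospital's scores. The
generator emulates *marginal* item quality only: real records correlate
defects across items (a truncated upload loses whole sections), carry
free-text narrative, and drift over time. Passing tests on synthetic
batches therefore demonstrates that the engine measures what it claims to
measure, not that any particular score will be observed on real data.

## Numerical and degenerate-input choices

* Half-up display rounding (`floor(x + 0.5)` on non-negatives), applied
  once, at the reporting boundary.
* Score formulas use plain double sums; with $X_i \le k_I \le$ a few tens
  and $n$ in the tens of thousands the sums are exact in doubles (integers
  far below $2^{53}$), so no rational arithmetic is needed.
* $n = 0$: error in every scoring path and a dedicated CLI exit code (2).
* Weights are validated to sum to 1 within $10^{-9}$.
* Duplicate record ids are kept and warned about — uploads are snapshots
  with no key constraint; deduplication is the caller's decision.
* Malformed ages (negative, non-integer) produce a parse warning and a
  missing field, never a dropped row: every input row is accounted for as
  exactly one record or one warning.
* Code-set files must be non-empty (an empty code range would vacuously
  fail every strict item and silently pass every lenient one).

## Validation problem sizes

The test suite runs the scoring oracle comparison on 200 random batches of
up to 50 records, ground-truth recovery on 100 random batch
specifications, the star oracle exhaustively on $2^5$ vectors plus 1,000
random 14-flag vectors, and one full-size synthetic batch of 28,348
records through the whole pipeline; `scripts/acceptance.R` repeats the
headline computations at the same sizes. These sizes give exact,
integer-valued expectations throughout while keeping a full run in the
low minutes on a single core.

## Known limitations

* The shipped code sets are invented fixtures; conclusions about real
  conformance require the real WS/GB value sets, loaded at runtime.
* The exact membership of the 14 published standards and the published
  batch-level aggregation formula are not recoverable; both are explicit,
  replaceable reconstructions here.
* No parsing of narrative Chinese clinical text into structured fields;
  records must arrive structured (delimited or JSON lines).
* Uniform item weighting only — every mandatory item costs the same
  $100/(n k_I)$, mirroring the uniform-denominator scores.
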