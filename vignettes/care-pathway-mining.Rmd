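---
title: "Mining surgical care pathways from administrative records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining surgical care pathways from administrative records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careflow)
```

## The problem and the model

A care pathway prescribes the sequence and timing of services a patient
group should receive; administrative data record what actually happened.
`careflow` targets the diagnostic segment of the breast cancer surgical
pathway — from the cyto-histological diagnosis to surgery — because it is
clinically predictable, guideline-bound (surgery within 30 days of the end
of diagnosis for the highest elective priority), and fully observable in
two routine data streams: inpatient discharge abstracts and outpatient
claims.

The analysis object is an *event log*: one trace per patient, each trace
an ordered sequence of day-stamped activities drawn from a 7-label
whitelist (Biopsy, Mammography, Ultrasound, Outpatient visit, and the
three surgery classes BCT, mastectomy, reconstruction). The model mined
from it is a *directly-follows graph*: activities as nodes, an edge
`A → B` whenever at least one patient performs `B` immediately after `A`
with no intermediate whitelisted activity. Each edge accumulates

* `occurrences` — total directly-follows pairs (self-loops included, so
  exam repetition is visible);
* `case coverage` — the number and percentage of patients traversing the
  edge at least once; percentages rather than absolute counts are the
  default labels because hospitals of very different volume must be
  comparable;
* the multiset of day gaps between the two events, summarised as median
  (default), mean or total. The median is preferred because waiting-time
  distributions have long upper tails; a 0-day value renders as
  `instant`.

Dashed arrows from an artificial start marker (and to an end marker)
record each trace's first and last activity; their case counts each sum
to the number of cases, a conservation property the tests enforce.

This is deliberately *not* a reimplementation of any proprietary fuzzy
miner: the package implements the documented behaviours of such maps —
dual frequency/performance views, mixed labels, importance zoom,
instant/dashed edges — as a compatibility target, with every rule stated
here explicitly.

## Cohort construction

An admission qualifies when a principal or secondary diagnosis is
malignant breast cancer (`174.x`; in-situ disease only as the exact code
`233.0`) and the procedure classifies as surgery (`85.2x` breast-conserving,
exactly `85.33`–`85.36` reconstruction, `85.4x` mastectomy), restricted to
elective surgery of the highest priority class. Six exclusion rules then
apply, in a fixed order with first-match attribution:
`out_of_region`, `multiple_surgeries`, `missing_priority`, `no_biopsy`,
`no_imaging` (no mammography/ultrasound in the lookback window
`(surgery − 365 d, surgery]`, closed on the right), `over_365_days`
(last-biopsy-to-surgery gap above 365 days, treated as an outlier).
The fixed order is a design choice — the rules could be stated in any
order — made so the exclusion report satisfies an exact conservation
identity (`n_input = n_kept + Σ counts`) and so every synthetic violator
is attributable to one rule in tests. Residency and "surgery outside the
regional system" are modelled as a single flag on the inpatient record,
since the registries that distinguish them are not part of the data
contract.

The trace window runs from the **last** biopsy (proxy for the end of
diagnosis; the exact diagnosis date is not recorded in claims) to the
surgery date. Consequently every trace begins with exactly one biopsy and
ends with exactly one surgery — a guarantee `build_event_log()` asserts
loudly rather than repairs. Case *duration* statistics are also offered
from the **first** biopsy (a proxy for the start of the diagnostic
work-up); the two modes are never mixed silently because they answer
different questions and can differ by weeks.

Records carry only the service day, never a time of day. Same-day events
are therefore ordered by a canonical convention — biopsy < mammography <
ultrasound < outpatient visit < surgery, then tariff code — chosen once so
that every downstream tie-break is deterministic and reproducible.

## Importance zoom

`zoom_map(map, path_zoom, activity_zoom)` keeps the top
`ceiling(activity_zoom · |A|)` activities by case coverage (ties by label)
and, among edges between kept activities, the top
`ceiling(path_zoom · |E|)` by occurrences (ties by source, then target).
A repair step then guarantees connectivity: while some kept activity is
unreachable from the start marker or cannot reach the end marker, the
highest-ranked dropped edge that strictly reduces the disconnection score
(the number of unreachable-from-start activities plus the number of
activities not reaching the end) is restored. Scoring the two directions
separately matters: a single edge often fixes only one direction, and a
greedy rule on "fully disconnected activities" alone can stall. When the
activity step has removed *all* neighbours of a kept activity no edge can
reconnect it; such activities are pruned (cascading) so the no-disconnected
guarantee is absolute. With both fractions at 1 the zoom is the identity;
the default `path_zoom = 0.8`, `activity_zoom = 1` trades a little
completeness for much interpretability. Whether a commercial slider at
"80%" keeps 80% of edges or applies a significance percentile is not
documented anywhere; the `ceiling(f · |E|)` reading is this package's own
definition, so maps produced by other tools should not be expected to
match edge-for-edge.

## Cost and variation tables

For each hospital (always the hospital of surgery, to which all of a
patient's events are attributed) and each exam category, the per-patient
cost distribution is summarised by median, mean and sample (n−1) standard
deviation. Patients with zero events of a category are included at cost
0 — otherwise mean × n would not equal observed spend, and the package
treats that identity (and its corollary, mean total cost = grand spend /
patients) as an exact invariant. `frequency` is exams per treated patient
(exactly 1 for biopsies on a windowed cohort, which the tests force;
above 1 where exams are repeated), and `types` counts distinct tariff
variants observed. Costs are expressed in scaled standardized euros: the
regional scaling factor is not public, so it is a configurable multiplier
(default 1) recorded in the output metadata. Note that per-patient visit
summaries in published tables sometimes show median = mean or SD = 0,
which no zero-inflated per-patient distribution can produce; this package
implements the stated definition and documents the discrepancy rather
than reverse-engineering an undocumented variant.

## The synthetic-data generator

Confidential regional data cannot ship with the package, so a seeded
generator emulates their statistical structure; it is first-class, tested
code, not a fixture.

* **Waiting times** are log-normal on day gaps, rounded to whole days,
  parameterized by (median, geometric SD). No distributional law is
  published for these gaps; the log-normal is chosen because regional
  waiting-time distributions are strongly right-skewed (medians near two
  months with upper quartiles more than twice the median are typical).
  Defaults use geometric SDs of 1.5–2.2.
* **Motifs**: a direct last-biopsy-to-surgery jump (no exam in between),
  repeated outpatient visits, a mammography+ultrasound same-day cluster,
  and same-day exam repetition, each Bernoulli per patient. Every trace
  starts with a biopsy and carries same-day imaging, so clean patients
  satisfy the imaging rule by construction.
* **Tariffs** are drawn from a catalog with four biopsy variants whose
  costs span two orders of magnitude, the cheap fine-needle variant being
  most likely — this is what makes biopsy cost distributions right-skewed
  (mean ≫ median).
* **Exclusion injection** mutates an otherwise-clean patient (clears the
  priority field, duplicates the surgery admission, deletes biopsy or
  imaging claims, pushes surgery past 365 days while adding one in-window
  imaging claim) rather than sampling a separate population, so each
  violator fails exactly one rule and exclusion reports can be checked
  against the injection ledger exactly.
* The demo configuration uses four hospitals of 260/250/110/45 patients —
  the high/high/medium/low volume spread typical of regional breast
  units, scaled down so analyses run in seconds — with direct-surgery
  probabilities 0.21/0.02/0.03/0.22, emulating the pattern where only
  some providers show an appreciable share of biopsy-straight-to-surgery
  patients. The calendar origin is fixed at
  2018-01-01; dates only, no time zones.

What the generator does **not** emulate: screening, chemotherapy,
radiotherapy and follow-up phases; coding errors and record-linkage
noise; seasonal throughput; correlation between cost variant choice and
waiting time. Passing tests therefore demonstrate the pipeline's
correctness on structurally realistic inputs, not calibration to any
hospital's published figures.

## Numerical conventions

* Percentiles (medians, IQRs) use linear interpolation between order
  statistics (`stats::quantile`, type 7), so reported values are
  bit-for-bit reproducible.
* The median of an even-sized gap multiset is the mean of the two central
  values.
* Negative day gaps are impossible after trace ordering and are asserted,
  not silently clamped.
* Edge pen-widths in DOT output scale affinely from 1 to 5 with the
  primary weight (constant 2.5 when all weights tie), preserving
  monotonicity.
* All randomness is funnelled through one seed (`withr::with_seed`), and
  the pipeline manifest hashes every artifact so end-to-end determinism
  is a testable property.

## Problem sizes used in the test-suite

Property suites run on deliberately modest sizes chosen as this package's
own verification conditions: 100 random small logs against a brute-force
directly-follows oracle; a 4 × 4 zoom-fraction grid over 20 random maps
with exhaustive path-existence checking; waiting-time medians of 5, 15
and 40 days recovered within ±2 days from cohorts of 1000 patients;
exclusion conservation on 400 mixed-injection patients plus six
single-rule cohorts of 50.

## Known limitations

* The miner consumes day-granular logs; sub-day ordering is conventional,
  and "instant" edges conflate genuinely simultaneous work with same-day
  sequences.
* Exclusion attribution depends on the stated rule order; counts per rule
  (not the kept set) would change under a different order.
* The zoom's edge-count semantics are this package's definition (see
  above); cross-tool comparisons should use the serialized map, not the
  rendered picture.
* No conformance checking, model repair or streaming analysis; the
  package discovers and describes, it does not judge deviations —
  deviations can be clinically justified, and their interpretation
  belongs to domain experts.
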