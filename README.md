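# careflow

Process mining of surgical care pathways from administrative health
records.

Hospitals that treat the same condition rarely run the same process. For
breast cancer, regional guidelines prescribe a tight diagnostic funnel —
biopsy, imaging, specialist visit, then surgery within 30 days of the end
of diagnosis for the highest surgical priority — but what actually happens
is only visible in administrative data: inpatient discharge abstracts
(ICD-9-CM diagnoses and procedures) and outpatient service claims (tariff
codes and costs). `careflow` reconstructs the *actual* pathway of every
surgical patient from those two record streams and renders it as a
directly-follows process map, so that analysts, hospital managers and
health-services researchers can see where patients wait, which exams are
repeated, and why diagnostic spending differs across providers.

The package covers the whole pipeline:

* **Cohort construction** — select admissions with a malignant breast
  cancer diagnosis (174.x, or in-situ 233.0) and a surgical procedure
  (85.2x conservative surgery, 85.33–85.36 reconstruction, 85.4x
  mastectomy), restricted to elective surgery of the highest priority;
  then apply six exclusion rules (out-of-region care, multiple surgeries,
  missing priority, no biopsy, no recent imaging, an over-365-day
  diagnosis-to-surgery gap) with first-match attribution, so that
  `n_input = n_kept + sum(exclusions)` always holds.
* **Event-log construction** — each kept patient becomes a trace running
  from the *last* biopsy (the best available proxy for the end of
  diagnosis) to surgery, at day granularity, restricted to a 7-activity
  whitelist (Biopsy, Mammography, Ultrasound, Outpatient visit, and the
  three surgery types). CSV and XES export are provided.
* **Process discovery** — a directly-follows graph: an edge `A → B`
  exists when at least one patient performs `B` immediately after `A`.
  Edges carry occurrence counts, case coverage (% of patients traversing
  the edge at least once) and the multiset of day gaps; the map renders as
  Graphviz DOT in a *frequency view*, a *performance view*
  (median/mean/total elapsed days; same-day transitions are `instant`), or
  a mixed view, with an importance zoom that keeps the top fraction of
  activities and paths while guaranteeing no depicted activity is
  disconnected.
* **Performance and cost statistics** — per-hospital case volumes, median
  case durations with interpolated IQRs, 30-day guideline adherence, and
  per-category cost tables (median/mean/SD per patient, exams per patient,
  distinct tariff variants) plus cross-hospital comparison tables.
* **Synthetic data** — a seeded generator of pseudo-administrative records
  (heterogeneous hospitals, log-normal waiting times, pathway motifs,
  injectable exclusion-rule violations) so the entire pipeline is testable
  without access to confidential regional data.

## Worked example

The two-patient illustrative log shipped with the package: both patients
start with a biopsy; only patient 1 goes directly from the biopsy to an
outpatient visit, 55 days later.

```r
library(careflow)
m <- mine_map(example_log())
m
#> <process_map> 6 activities, 6 directly-follows edges, 2 cases
m$edges[, c("source", "target", "occurrences", "coverage_pct")]
#> # A tibble: 6 × 4
#>   source           target           occurrences coverage_pct
#>   <chr>            <chr>                  <int>        <dbl>
#> 1 Biopsy           Mammography                1           50
#> 2 Biopsy           Outpatient visit           1           50
#> 3 Mammography      Ultrasound                 1           50
#> 4 Outpatient visit BCT                        1           50
#> 5 Outpatient visit Mastectomy                 1           50
#> 6 Ultrasound       Outpatient visit           1           50
edge_statistic(m, "Biopsy", "Outpatient visit", "median")
#> [1] 55
```

The `Biopsy → Outpatient visit` edge is traversed by one of the two cases
(coverage 50%) with a median elapsed time of 55 days — the longest gap in
the log, and the edge a frequency/performance map draws thickest.
`render_dot(m)` emits the corresponding Graphviz source.

A full synthetic four-hospital analysis:

```r
out <- file.path(tempdir(), "demo")
run_pipeline(pipeline_config(out, generator = demo_config(seed = 42)))
readr::read_csv(file.path(out, "hospital_summary.csv"))
#>   hospital_id n_patients n_events avg_events_per_patient median_case_duration_days share_of_total_cases
#> 1          H1        260     1074                    4.1                      61.5                39.10
#> 2          H2        250     1245                    5.0                      57.0                37.59
#> 3          H3        110      546                    5.0                      49.0                16.54
#> 4          H4         45      202                    4.5                      88.0                 6.77
readr::read_csv(file.path(out, "mean_total_cost.csv"))
#>   hospital_id mean_total_cost
#> 1          H1           23.95
#> 2          H2           24.81
#> 3          H3           25.98
#> 4          H4           25.94
```

Hospitals are anonymized H1…Hn by descending volume (sidecar
`hospital_mapping.csv`). Median case duration counts days from the first
biopsy to surgery; the mean total cost is the per-patient diagnostic spend
in scaled euros, i.e. the sum over exam categories of mean per-patient
cost. The output directory also contains per-hospital event logs (CSV and
XES), frequency- and performance-view DOT maps zoomed to the 80% most
frequent paths, duration, adherence and cost tables, the three
cross-hospital comparison tables, and a `manifest.csv` of MD5 hashes
(identical across reruns with the same seed).

## Further reading

The methods vignette (`vignettes/care-pathway-mining.Rmd`) documents the
model and its assumptions, the synthetic-data generator's design, the
numerical conventions (percentile interpolation, tie-breaking, zoom
repair), and known limitations.
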