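#' Pipeline configuration
#'
#' Exactly one input source must be supplied: either a generator
#' configuration (synthetic records) or the paths of the two raw record
#' CSVs.
#'
#' @param out_dir output directory for all artifacts.
#' @param generator a [generator_config()], or `NULL`.
#' @param inpatient_csv,outpatient_csv raw record CSV paths, or `NULL`.
#' @param catalog tariff catalog used for classification and costing.
#' @param view a [view_config()] controlling map rendering and zoom.
#' @param scale cost scaling factor passed to [cost_summary()].
#' @param seed overrides the generator seed when supplied.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            generator = NULL,
                            inpatient_csv = NULL, outpatient_csv = NULL,
                            catalog = default_catalog(),
                            view = view_config(),
                            scale = 1,
                            seed = NULL) {
  from_files <- !is.null(inpatient_csv) || !is.null(outpatient_csv)
  if (is.null(generator) == !from_files) {
    abort("pipeline_config: supply exactly one of `generator` or the two record CSV paths")
  }
  if (from_files && (is.null(inpatient_csv) || is.null(outpatient_csv))) {
    abort("pipeline_config: both inpatient_csv and outpatient_csv are required")
  }
  if (!is.null(generator) && !is.null(seed)) {
    generator$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, generator = generator,
                 inpatient_csv = inpatient_csv,
                 outpatient_csv = outpatient_csv,
                 catalog = catalog, view = view, scale = scale),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full care-pathway analysis pipeline
#'
#' Orchestrates record ingestion (or generation), cohort selection, the six
#' exclusion rules, event-log construction, per-hospital process-map
#' discovery with importance zoom, waiting-time and adherence statistics,
#' cost summaries, and cross-hospital comparison tables. Hospitals are
#' anonymized at report time as H1, H2, ... in descending order of volume;
#' the mapping is written as a sidecar file.
#'
#' Artifacts written under `config$out_dir`: raw records (when generated),
#' the exclusion report, per-hospital event logs (CSV and XES), frequency-
#' and performance-view DOT maps and a JSON map per hospital, hospital
#' summary, duration, adherence and cost-summary tables, the three
#' comparison tables, and a `manifest.csv` listing every artifact with its
#' MD5 content hash. A fixed seed yields identical manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest tibble (`file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  catalog <- config$catalog

  records <- run_stage("ingest", {
    if (!is.null(config$generator)) {
      rec <- generate_cohort(config$generator)
      write_records_csv(rec, file.path(out, "inpatient.csv"),
                        file.path(out, "outpatient.csv"))
      rec
    } else {
      read_records_csv(config$inpatient_csv, config$outpatient_csv)
    }
  })

  filtered <- run_stage("cohort", {
    cases0 <- select_cases(records$inpatient)
    apply_exclusions(cases0, records$outpatient, catalog)
  })
  readr::write_csv(as.data.frame(filtered$report),
                   file.path(out, "exclusion_report.csv"))

  log <- run_stage("event_log",
                   build_event_log(filtered$cases, records$outpatient, catalog))

  # report-time anonymization: H1..Hn by descending case volume
  vol <- filtered$cases %>% count(.data$hospital_id, sort = TRUE)
  mapping <- tibble(hospital_id = vol$hospital_id,
                    anonymized_id = paste0("H", seq_len(nrow(vol))))
  readr::write_csv(mapping, file.path(out, "hospital_mapping.csv"))
  rename_h <- setNames(mapping$anonymized_id, mapping$hospital_id)
  cases <- filtered$cases %>%
    mutate(hospital_id = unname(rename_h[.data$hospital_id]))
  log <- as_event_log(as_tibble(log) %>%
    mutate(hospital_id = unname(rename_h[.data$hospital_id]),
           case_id = .data$case_id))

  run_stage("discovery", {
    for (h in mapping$anonymized_id) {
      hlog <- as_event_log(as_tibble(log) %>% filter(.data$hospital_id == h))
      write_log_csv(hlog, file.path(out, sprintf("event_log_%s.csv", h)))
      export_xes(hlog, file.path(out, sprintf("event_log_%s.xes", h)))
      m <- zoom_map(mine_map(hlog), config$view$path_zoom,
                    config$view$activity_zoom)
      writeLines(render_dot(m, view_config("frequency", config$view$statistic,
                                           mixed = config$view$mixed)),
                 file.path(out, sprintf("map_%s_frequency.dot", h)))
      writeLines(render_dot(m, view_config("performance", config$view$statistic,
                                           mixed = config$view$mixed)),
                 file.path(out, sprintf("map_%s_performance.dot", h)))
      map_to_json(m, file.path(out, sprintf("map_%s.json", h)))
    }
  })

  run_stage("statistics", {
    readr::write_csv(hospital_summary(log, cases),
                     file.path(out, "hospital_summary.csv"))
    durs <- bind_rows(case_durations(cases, "from_first_biopsy"),
                      case_durations(cases, "from_last_biopsy")) %>%
      select(-"durations")
    readr::write_csv(durs, file.path(out, "case_durations.csv"))
    readr::write_csv(adherence_30d(cases), file.path(out, "adherence_30d.csv"))
  })

  cs <- run_stage("costs", {
    cs <- cost_summary(log, catalog, scale = config$scale)
    readr::write_csv(as_tibble(cs), file.path(out, "cost_summary.csv"))
    readr::write_csv(mean_total_cost(cs), file.path(out, "mean_total_cost.csv"))
    cs
  })

  run_stage("comparison", {
    if (n_distinct(cs$hospital_id) >= 2) {
      cmp <- compare_hospitals(cs)
      readr::write_csv(cmp %>% filter(.data$metric == "frequency"),
                       file.path(out, "comparison_frequency.csv"))
      readr::write_csv(cmp %>% filter(.data$metric == "mean_cost"),
                       file.path(out, "comparison_mean_cost.csv"))
      readr::write_csv(cmp %>% filter(.data$metric == "mean_total_cost"),
                       file.path(out, "comparison_mean_total_cost.csv"))
    }
  })

  files <- sort(setdiff(list.files(out), "manifest.csv"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))))
  readr::write_csv(manifest, file.path(out, "manifest.csv"))
  invisible(manifest)
}
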