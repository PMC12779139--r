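#' Classify an ICD-9-CM procedure code as a surgery type
#'
#' Breast-conserving therapy is any `85.2x` code, reconstructive surgery the
#' exact codes `85.33`-`85.36`, and mastectomy any `85.4x` code. Codes
#' outside these families are no-match and return `NA` (not an error):
#' callers use the no-match signal to skip non-surgical admissions.
#'
#' @param procedure_code character vector of ICD-9-CM procedure codes.
#' @return character vector: `"BCT"`, `"reconstruction"`, `"mastectomy"`, or
#'   `NA` for no-match.
#' @export
#' @examples
#' classify_surgery(c("85.21", "85.34", "85.42", "85.50"))
classify_surgery <- function(procedure_code) {
  stopifnot(is.character(procedure_code))
  out <- rep(NA_character_, length(procedure_code))
  out[startsWith(procedure_code, "85.2")] <- "BCT"
  out[procedure_code %in% c("85.33", "85.34", "85.35", "85.36")] <- "reconstruction"
  out[startsWith(procedure_code, "85.4")] <- "mastectomy"
  out[is.na(procedure_code)] <- NA_character_
  out
}

# Malignant breast cancer: any 174.x; in-situ: exact 233.0 only.
is_breast_dx <- function(dx) {
  !is.na(dx) & (startsWith(dx, "174") | dx == "233.0")
}

#' Select qualifying surgery cases from inpatient records
#'
#' Emits one case per qualifying surgery admission: a principal or secondary
#' diagnosis of malignant breast cancer (174.x) or localized in-situ cancer
#' (233.0), a procedure classified by [classify_surgery()], and elective
#' surgery of the highest priority class. Admissions whose priority field is
#' missing are kept here and attributed to the `missing_priority` exclusion
#' rule downstream, so that the exclusion report can account for them.
#'
#' Malformed rows (missing patient id, hospital or dates, or admission after
#' discharge) are skipped with a warning naming the row numbers.
#'
#' @param inpatient tibble of inpatient discharge records (see
#'   [generate_cohort()] for the schema).
#' @param priority_class value of `priority` denoting the highest elective
#'   class (default `"P1"`).
#' @return tibble of surgery cases: `patient_id`, `hospital_id`,
#'   `surgery_date`, `surgery_type`, `priority`, `resident_flag`,
#'   `first_biopsy_date`, `last_biopsy_date` (biopsy dates filled by
#'   [apply_exclusions()]).
#' @export
select_cases <- function(inpatient, priority_class = "P1") {
  x <- as_tibble(inpatient)
  bad <- which(
    is.na(x$patient_id) | is.na(x$hospital_id) |
      is.na(x$admission_date) | is.na(x$discharge_date) |
      x$admission_date > x$discharge_date |
      (!is.na(x$procedure_code) & is.na(x$procedure_date)))
  if (length(bad)) {
    warn(sprintf("select_cases: skipping %d malformed inpatient row(s): %s",
                 length(bad), paste(head(bad, 20L), collapse = ", ")))
    x <- x[-bad, ]
  }
  stype <- classify_surgery(x$procedure_code)
  keep <- (is_breast_dx(x$principal_dx) | is_breast_dx(x$secondary_dx)) &
    !is.na(stype) &
    (is.na(x$priority) | x$priority == priority_class)
  x <- x[keep, ]
  tibble(
    patient_id = x$patient_id,
    hospital_id = x$hospital_id,
    surgery_date = x$procedure_date,
    surgery_type = stype[keep],
    priority = x$priority,
    resident_flag = x$resident_flag,
    first_biopsy_date = as.Date(NA),
    last_biopsy_date = as.Date(NA))
}

#' Apply the six cohort exclusion rules
#'
#' Rules are evaluated per patient in a fixed order and the first failing
#' rule is the one attributed, so every excluded patient is counted exactly
#' once and `n_input = n_kept + sum(per-rule counts)` always holds:
#'
#' 1. `out_of_region`: non-resident, or surgery outside the regional system
#'    (both carried as `resident_flag = FALSE`);
#' 2. `multiple_surgeries`: more than one qualifying surgery admission;
#' 3. `missing_priority`: no surgical priority recorded;
#' 4. `no_biopsy`: no biopsy-tariff outpatient service on or before the
#'    surgery date;
#' 5. `no_imaging`: no mammography or ultrasound within the lookback window
#'    `(surgery_date - imaging_window_days, surgery_date]`;
#' 6. `over_365_days`: last-biopsy-to-surgery gap above `max_gap_days`
#'    (treated as an outlier).
#'
#' Kept cases get `first_biopsy_date` and `last_biopsy_date` filled from the
#' outpatient stream.
#'
#' @param cases output of [select_cases()].
#' @param outpatient tibble of outpatient service records.
#' @param catalog tariff catalog mapping tariff codes to exam categories.
#' @param max_gap_days outlier threshold on the last-biopsy-to-surgery gap.
#' @param imaging_window_days imaging lookback window length.
#' @return list with `cases` (kept cases, one row per patient, biopsy dates
#'   filled) and `report` (an `exclusion_report`: per-rule counts, `n_input`,
#'   `n_kept`, and a `details` tibble with one row per input patient).
#' @export
apply_exclusions <- function(cases, outpatient,
                             catalog = default_catalog(),
                             max_gap_days = 365,
                             imaging_window_days = 365) {
  cat_map <- catalog_category_map(catalog)
  op <- as_tibble(outpatient)
  op$category <- unname(cat_map[op$tariff_code])

  pat <- cases %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_surg = n(),
      any_nonresident = any(!.data$resident_flag),
      any_missing_priority = any(is.na(.data$priority)),
      surgery_date = min(.data$surgery_date),
      .groups = "drop")

  biops <- op %>%
    filter(.data$category == "biopsy") %>%
    left_join(pat %>% select("patient_id", "surgery_date"), by = "patient_id") %>%
    filter(!is.na(.data$surgery_date), .data$service_date <= .data$surgery_date) %>%
    group_by(.data$patient_id) %>%
    # sort-and-subscript instead of min/max: safe on dplyr's empty prototype
    summarise(first_biopsy_date = sort(.data$service_date)[1],
              last_biopsy_date = sort(.data$service_date,
                                      decreasing = TRUE)[1],
              .groups = "drop")

  imaging <- op %>%
    filter(.data$category %in% c("mammography", "ultrasound")) %>%
    left_join(pat %>% select("patient_id", "surgery_date"), by = "patient_id") %>%
    filter(!is.na(.data$surgery_date),
           .data$service_date <= .data$surgery_date,
           .data$service_date > .data$surgery_date - imaging_window_days) %>%
    distinct(.data$patient_id) %>%
    mutate(has_imaging = TRUE)

  pat <- pat %>%
    left_join(biops, by = "patient_id") %>%
    left_join(imaging, by = "patient_id") %>%
    mutate(
      has_imaging = !is.na(.data$has_imaging),
      gap = as.integer(.data$surgery_date - .data$last_biopsy_date),
      rule = dplyr::case_when(
        .data$any_nonresident ~ "out_of_region",
        .data$n_surg > 1 ~ "multiple_surgeries",
        .data$any_missing_priority ~ "missing_priority",
        is.na(.data$last_biopsy_date) ~ "no_biopsy",
        !.data$has_imaging ~ "no_imaging",
        .data$gap > max_gap_days ~ "over_365_days",
        TRUE ~ NA_character_))

  kept_ids <- pat$patient_id[is.na(pat$rule)]
  kept <- cases %>%
    filter(.data$patient_id %in% kept_ids) %>%
    select(-"first_biopsy_date", -"last_biopsy_date") %>%
    left_join(biops, by = "patient_id") %>%
    arrange(.data$patient_id)

  counts <- vapply(exclusion_rule_ids(),
                   function(r) sum(pat$rule == r, na.rm = TRUE), integer(1))
  report <- structure(
    list(counts = counts,
         n_input = nrow(pat),
         n_kept = length(kept_ids),
         details = pat %>% select("patient_id", "rule")),
    class = "exclusion_report")
  list(cases = kept, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> ", x$n_input, " patients in, ", x$n_kept,
      " kept, ", sum(x$counts), " excluded\n", sep = "")
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0) cat("  ", format(r, width = 20), x$counts[[r]], "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.exclusion_report <- function(x, ...) {
  data.frame(rule = names(x$counts), n_excluded = unname(x$counts),
             row.names = NULL)
}

#' Construct an event log from tabular event data
#'
#' Light constructor used by the readers and by tests: orders events
#' chronologically within case (same-day ties in the canonical activity
#' order, then tariff code) and attaches the `event_log` class. No pathway
#' validation is performed; [build_event_log()] is the validating producer.
#'
#' @param events tibble with columns `case_id`, `activity`, `date`,
#'   `hospital_id`, `tariff_code`, `cost`.
#' @return an `event_log` tibble.
#' @export
as_event_log <- function(events) {
  ev <- as_tibble(events)
  needed <- c("case_id", "activity", "date", "hospital_id", "tariff_code", "cost")
  missing <- setdiff(needed, names(ev))
  if (length(missing)) {
    abort(paste0("event log is missing column(s): ", paste(missing, collapse = ", ")))
  }
  ev <- ev[needed]
  ev <- ev[order(ev$case_id, ev$date, activity_rank(ev$activity),
                 ev$tariff_code, method = "radix"), ]
  class(ev) <- c("event_log", class(tibble()))
  ev
}

#' Build the last-biopsy-to-surgery event log
#'
#' For each kept case, the trace is the whitelisted outpatient activities
#' with `last_biopsy_date <= date <= surgery_date`, plus the surgery event
#' itself. Outpatient services whose tariff code is not in the catalog
#' (e.g. pre-surgery electrocardiography or post-surgery follow-up exams)
#' are dropped. All events of a case are attributed to the hospital where
#' the patient had surgery, which is the grouping key of every downstream
#' comparison. By construction each trace starts with exactly one biopsy
#' (the last one) and ends with exactly one surgery; the function fails
#' loudly if the input violates this.
#'
#' @param cases kept cases from [apply_exclusions()] (biopsy dates filled).
#' @param outpatient outpatient service records.
#' @param catalog tariff catalog.
#' @return an `event_log` tibble with columns `case_id`, `activity`, `date`,
#'   `hospital_id`, `tariff_code`, `cost`.
#' @export
build_event_log <- function(cases, outpatient, catalog = default_catalog()) {
  if (any(is.na(cases$last_biopsy_date))) {
    abort("build_event_log: cases must have biopsy dates filled (run apply_exclusions first)")
  }
  cat_map <- catalog_category_map(catalog)
  op <- as_tibble(outpatient)
  op$category <- unname(cat_map[op$tariff_code])
  op <- op %>%
    filter(!is.na(.data$category)) %>%
    left_join(cases %>% select("patient_id", "hospital_id", "surgery_date",
                               "last_biopsy_date"),
              by = "patient_id") %>%
    filter(!is.na(.data$surgery_date),
           .data$service_date >= .data$last_biopsy_date,
           .data$service_date <= .data$surgery_date)

  ev <- bind_rows(
    tibble(case_id = op$patient_id,
           activity = category_label(op$category),
           date = op$service_date,
           hospital_id = op$hospital_id,
           tariff_code = op$tariff_code,
           cost = op$cost),
    tibble(case_id = cases$patient_id,
           activity = surgery_type_label(cases$surgery_type),
           date = cases$surgery_date,
           hospital_id = cases$hospital_id,
           tariff_code = NA_character_,
           cost = NA_real_))
  log <- as_event_log(ev)
  validate_event_log(log)
  log
}

# Windowing guarantee: one biopsy first, one surgery last, dates
# nondecreasing. Violations indicate corrupted input, so fail loudly.
validate_event_log <- function(log) {
  chk <- log %>%
    group_by(.data$case_id) %>%
    summarise(
      first_ok = dplyr::first(.data$activity) == "Biopsy",
      last_ok = dplyr::last(.data$activity) %in% surgery_labels(),
      one_biopsy = sum(.data$activity == "Biopsy") == 1L,
      one_surgery = sum(.data$activity %in% surgery_labels()) == 1L,
      sorted = !is.unsorted(.data$date),
      .groups = "drop")
  bad <- chk$case_id[!(chk$first_ok & chk$last_ok & chk$one_biopsy &
                         chk$one_surgery & chk$sorted)]
  if (length(bad)) {
    abort(paste0("event log violates the windowing guarantee for case(s): ",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  invisible(log)
}
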