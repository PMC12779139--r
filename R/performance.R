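#' Biopsy-to-surgery case durations per hospital
#'
#' Case duration is the number of days from biopsy to surgery. Two
#' definitions are exposed and never silently mixed: `from_first_biopsy`
#' (the first biopsy proxies the start of the diagnostic work-up; the
#' definition used in the per-hospital summary tables) and
#' `from_last_biopsy` (the last biopsy proxies the end of diagnosis; the
#' definition used for guideline adherence). Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7), so
#' reported IQRs are reproducible bit-for-bit.
#'
#' @param cases kept cases with both biopsy dates filled.
#' @param mode `"from_first_biopsy"` or `"from_last_biopsy"`.
#' @return tibble with one row per hospital: `hospital_id`, `mode`,
#'   `n_cases`, `median_days`, `q25`, `q75`, and `durations` (list column of
#'   per-case day counts).
#' @export
case_durations <- function(cases,
                           mode = c("from_first_biopsy", "from_last_biopsy")) {
  mode <- match.arg(mode)
  ref <- if (mode == "from_first_biopsy") cases$first_biopsy_date
         else cases$last_biopsy_date
  if (any(is.na(ref))) {
    abort("case_durations: cases must carry biopsy dates (run apply_exclusions first)")
  }
  tibble(hospital_id = cases$hospital_id,
         duration = as.integer(cases$surgery_date - ref)) %>%
    group_by(.data$hospital_id) %>%
    summarise(mode = !!mode,
              n_cases = n(),
              median_days = stats::median(.data$duration),
              q25 = unname(quantile(.data$duration, 0.25, type = 7)),
              q75 = unname(quantile(.data$duration, 0.75, type = 7)),
              durations = list(.data$duration),
              .groups = "drop") %>%
    arrange(.data$hospital_id)
}

#' Per-hospital cohort summary
#'
#' One row per hospital (grouped by the hospital where the patient had
#' surgery): number of patients, number of logged events, average events per
#' patient (one decimal), median case duration from the first biopsy, and
#' the hospital's share of all cases.
#'
#' @param log the event log.
#' @param cases the kept cases backing the log.
#' @return tibble `hospital_id`, `n_patients`, `n_events`,
#'   `avg_events_per_patient`, `median_case_duration_days`,
#'   `share_of_total_cases` (percent), sorted by volume (descending).
#' @export
hospital_summary <- function(log, cases) {
  ev <- as_tibble(log) %>% count(.data$hospital_id, name = "n_events")
  pats <- cases %>% count(.data$hospital_id, name = "n_patients")
  dur <- case_durations(cases, "from_first_biopsy") %>%
    select("hospital_id", median_case_duration_days = "median_days")
  pats %>%
    left_join(ev, by = "hospital_id") %>%
    left_join(dur, by = "hospital_id") %>%
    mutate(n_events = dplyr::coalesce(.data$n_events, 0L),
           avg_events_per_patient = round(.data$n_events / .data$n_patients, 1),
           share_of_total_cases = 100 * .data$n_patients / sum(.data$n_patients)) %>%
    select("hospital_id", "n_patients", "n_events", "avg_events_per_patient",
           "median_case_duration_days", "share_of_total_cases") %>%
    arrange(dplyr::desc(.data$n_patients), .data$hospital_id)
}

#' Guideline adherence: surgery within 30 days of diagnosis
#'
#' The regional guideline requires surgery no more than 30 days after the
#' end of the diagnosis for the highest surgical priority. With the last
#' biopsy as the diagnosis-date proxy, adherence is the fraction of cases
#' whose last-biopsy-to-surgery gap is at most `threshold_days` (closed
#' threshold).
#'
#' @param cases kept cases with `last_biopsy_date` filled.
#' @param threshold_days guideline interval in days (default 30).
#' @return tibble `hospital_id`, `n_cases`, `adherence` (fraction in
#'   \[0, 1\]).
#' @export
adherence_30d <- function(cases, threshold_days = 30) {
  gap <- as.integer(cases$surgery_date - cases$last_biopsy_date)
  if (any(is.na(gap))) {
    abort("adherence_30d: cases must carry last_biopsy_date")
  }
  tibble(hospital_id = cases$hospital_id, within = gap <= threshold_days) %>%
    group_by(.data$hospital_id) %>%
    summarise(n_cases = n(), adherence = mean(.data$within),
              .groups = "drop") %>%
    arrange(.data$hospital_id)
}
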