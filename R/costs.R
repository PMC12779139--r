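#' Per-patient cost by exam category
#'
#' Sums the tariff costs of each case's in-window events for every exam
#' category. Every case appears for every category, with cost 0 and 0
#' events when the patient had none: per-patient cost distributions must
#' include zero-cost patients for the category mean times the patient count
#' to equal the observed total spend. Surgery events carry no tariff and
#' are excluded.
#'
#' @param log the event log.
#' @param catalog tariff catalog (defines the category of each tariff
#'   code).
#' @return tibble `case_id`, `hospital_id`, `category`, `cost`, `n_events`,
#'   one row per case x category.
#' @export
per_patient_cost <- function(log, catalog = default_catalog()) {
  ev <- as_tibble(log)
  cat_map <- catalog_category_map(catalog)
  exams <- ev %>%
    filter(!.data$activity %in% surgery_labels()) %>%
    mutate(category = unname(cat_map[.data$tariff_code]))
  if (any(is.na(exams$category))) {
    abort("per_patient_cost: event log contains tariff codes absent from the catalog")
  }
  sums <- exams %>%
    group_by(.data$case_id, .data$category) %>%
    summarise(cost = sum(.data$cost), n_events = n(), .groups = "drop")
  tidyr::crossing(distinct(ev, .data$case_id, .data$hospital_id),
                  category = exam_categories()) %>%
    left_join(sums, by = c("case_id", "category")) %>%
    mutate(cost = dplyr::coalesce(.data$cost, 0),
           n_events = dplyr::coalesce(.data$n_events, 0L)) %>%
    arrange(.data$case_id, .data$category)
}

#' Per-hospital cost and variation summary
#'
#' For each hospital and exam category: the median, mean and sample
#' standard deviation (n - 1) of the per-patient cost distribution
#' (zero-cost patients included), the frequency (number of exams divided by
#' number of treated patients — exactly 1 for biopsies on a filtered,
#' windowed cohort, and above 1 when exams are repeated), and the number of
#' distinct tariff variants observed. Costs are multiplied by `scale`
#' (scaled standardized euros are defined up to a regional factor; the
#' factor used is recorded in the `scale` attribute of the result).
#'
#' @param log the event log.
#' @param catalog tariff catalog.
#' @param scale cost scaling factor (default 1).
#' @return tibble of class `cost_summary`: `hospital_id`, `category`,
#'   `median_cost`, `mean_cost`, `sd_cost`, `frequency`, `types`,
#'   `n_patients`.
#' @export
cost_summary <- function(log, catalog = default_catalog(), scale = 1) {
  pp <- per_patient_cost(log, catalog)
  ev <- as_tibble(log)
  cat_map <- catalog_category_map(catalog)
  types <- ev %>%
    filter(!.data$activity %in% surgery_labels()) %>%
    mutate(category = unname(cat_map[.data$tariff_code])) %>%
    group_by(.data$hospital_id, .data$category) %>%
    summarise(types = n_distinct(.data$tariff_code), .groups = "drop")

  out <- pp %>%
    group_by(.data$hospital_id, .data$category) %>%
    summarise(
      median_cost = stats::median(.data$cost) * !!scale,
      mean_cost = mean(.data$cost) * !!scale,
      sd_cost = stats::sd(.data$cost) * !!scale,
      frequency = sum(.data$n_events) / n(),
      n_patients = n(),
      .groups = "drop") %>%
    left_join(types, by = c("hospital_id", "category")) %>%
    mutate(types = dplyr::coalesce(.data$types, 0L)) %>%
    select("hospital_id", "category", "median_cost", "mean_cost", "sd_cost",
           "frequency", "types", "n_patients") %>%
    arrange(.data$hospital_id, .data$category)
  attr(out, "scale") <- scale
  class(out) <- c("cost_summary", class(out))
  out
}

#' Mean total diagnostic cost per patient
#'
#' The sum over the four exam categories of the mean per-patient cost,
#' which algebraically equals the grand diagnostic spend divided by the
#' number of patients (and equals the sum of mean cost per exam times exam
#' frequency).
#'
#' @param summary a [cost_summary()] result.
#' @return tibble `hospital_id`, `mean_total_cost`.
#' @export
mean_total_cost <- function(summary) {
  as_tibble(summary) %>%
    group_by(.data$hospital_id) %>%
    summarise(mean_total_cost = sum(.data$mean_cost), .groups = "drop") %>%
    arrange(.data$hospital_id)
}

#' Long-format comparison tables across hospitals
#'
#' Reshapes per-hospital cost summaries into long tables (hospital,
#' category, metric, value) for between-hospital comparison of exam
#' frequencies, mean per-patient costs, and the mean total cost per patient.
#'
#' @param summary a [cost_summary()] covering at least two hospitals.
#' @return tibble `hospital_id`, `category`, `metric`, `value`; the total
#'   cost rows use category `"all"`.
#' @export
compare_hospitals <- function(summary) {
  s <- as_tibble(summary)
  if (n_distinct(s$hospital_id) < 2) {
    abort("compare_hospitals: at least two hospitals are required")
  }
  bind_rows(
    s %>% select("hospital_id", "category", value = "frequency") %>%
      mutate(metric = "frequency"),
    s %>% select("hospital_id", "category", value = "mean_cost") %>%
      mutate(metric = "mean_cost"),
    mean_total_cost(s) %>%
      mutate(category = "all", metric = "mean_total_cost") %>%
      select("hospital_id", "category", value = "mean_total_cost", "metric")
  ) %>%
    select("hospital_id", "category", "metric", "value") %>%
    arrange(.data$metric, .data$hospital_id, .data$category)
}
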