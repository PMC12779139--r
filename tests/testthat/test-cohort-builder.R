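test_that("surgery classification follows the ICD-9-CM code families", {
  expect_equal(classify_surgery("85.21"), "BCT")
  expect_equal(classify_surgery("85.25"), "BCT")
  expect_equal(classify_surgery("85.34"), "reconstruction")
  expect_equal(classify_surgery(c("85.33", "85.36")),
               c("reconstruction", "reconstruction"))
  expect_equal(classify_surgery("85.41"), "mastectomy")
  expect_equal(classify_surgery("85.47"), "mastectomy")
  # no-match is NA, not an error
  expect_true(is.na(classify_surgery("85.50")))
  expect_true(is.na(classify_surgery("86.22")))
})

make_inpatient <- function(...) {
  defaults <- list(patient_id = "p1", hospital_id = "H",
                   admission_date = as.Date("2018-05-01"),
                   discharge_date = as.Date("2018-05-03"),
                   principal_dx = "174.9", secondary_dx = NA_character_,
                   procedure_code = "85.21",
                   procedure_date = as.Date("2018-05-01"),
                   priority = "P1", resident_flag = TRUE)
  args <- list(...)
  rows <- lapply(if (length(args) && is.list(args[[1]]) && !is.data.frame(args[[1]]))
                   args else list(args),
                 function(over) {
                   d <- defaults; d[names(over)] <- over
                   tibble::as_tibble(d)
                 })
  dplyr::bind_rows(rows)
}

test_that("case selection matches diagnosis and procedure code families", {
  # in-situ 233.0 with conservative surgery and highest priority -> one case
  one <- select_cases(make_inpatient(principal_dx = "233.0"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$surgery_type, "BCT")

  # non-breast diagnosis -> no case, even with a breast procedure
  expect_equal(nrow(select_cases(make_inpatient(principal_dx = "153.4"))), 0L)
  # 233.x other than 233.0 does not qualify
  expect_equal(nrow(select_cases(make_inpatient(principal_dx = "233.1"))), 0L)
  # breast code in secondary position qualifies
  expect_equal(nrow(select_cases(make_inpatient(principal_dx = "401.9",
                                                secondary_dx = "174.4"))), 1L)
  # non-surgical procedure -> no case
  expect_equal(nrow(select_cases(make_inpatient(procedure_code = "87.37"))), 0L)
  # lower elective priority -> outside the cohort
  expect_equal(nrow(select_cases(make_inpatient(priority = "P2"))), 0L)
  # missing priority passes through (attributed by the exclusion stage)
  expect_equal(nrow(select_cases(make_inpatient(priority = NA_character_))), 1L)
})

test_that("malformed inpatient rows are skipped with a warning naming them", {
  rows <- make_inpatient(list(), list(patient_id = NA_character_),
                         list(admission_date = as.Date("2018-06-01"),
                              discharge_date = as.Date("2018-05-01")))
  expect_warning(cases <- select_cases(rows), "2 malformed.*2, 3")
  expect_equal(nrow(cases), 1L)
})

test_that("selected case counts match an independent row scan on synthetic records", {
  rec <- generate_cohort(one_hospital_config(50, seed = 31))
  cases <- select_cases(rec$inpatient)
  # brute-force re-scan with none of the package's helpers
  df <- as.data.frame(rec$inpatient)
  n_expect <- 0L
  for (i in seq_len(nrow(df))) {
    dx_ok <- function(d) !is.na(d) && (substr(d, 1, 3) == "174" || d == "233.0")
    p <- df$procedure_code[i]
    proc_ok <- grepl("^85\\.2", p) || p %in% c("85.33", "85.34", "85.35", "85.36") ||
      grepl("^85\\.4", p)
    if ((dx_ok(df$principal_dx[i]) || dx_ok(df$secondary_dx[i])) && proc_ok)
      n_expect <- n_expect + 1L
  }
  expect_equal(nrow(cases), n_expect)
})

outpatient_row <- function(pid, date, code, cost = 1) {
  tibble::tibble(patient_id = pid, provider_id = "H",
                 service_date = as.Date("2018-01-01") + date,
                 tariff_code = code, cost = cost)
}

clean_fixture <- function() {
  # surgery day 60; biopsies day 0 and 20; mammography day 30; visit day 40
  inp <- make_inpatient(admission_date = as.Date("2018-01-01") + 60,
                        discharge_date = as.Date("2018-01-01") + 62,
                        procedure_date = as.Date("2018-01-01") + 60)
  outp <- dplyr::bind_rows(
    outpatient_row("p1", 0, "B-FNA", 0.71),
    outpatient_row("p1", 20, "B-ECR", 8.40),
    outpatient_row("p1", 30, "M-MONO", 2.36),
    outpatient_row("p1", 40, "V-FIRST", 5.43))
  list(inpatient = inp, outpatient = outp)
}

test_that("a clean case is kept with all exclusion counts zero and biopsy dates filled", {
  fx <- clean_fixture()
  res <- apply_exclusions(select_cases(fx$inpatient), fx$outpatient)
  expect_equal(res$report$n_kept, 1L)
  expect_true(all(res$report$counts == 0L))
  expect_equal(res$cases$first_biopsy_date, as.Date("2018-01-01"))
  expect_equal(res$cases$last_biopsy_date, as.Date("2018-01-21"))
})

test_that("each exclusion rule fires on its construction and order resolves overlaps", {
  fx <- clean_fixture()
  run <- function(inp, outp) {
    res <- apply_exclusions(select_cases(inp), outp)
    rules <- names(res$report$counts)[res$report$counts > 0]
    list(kept = res$report$n_kept, rules = rules)
  }

  r <- run(make_inpatient(resident_flag = FALSE,
                          procedure_date = fx$inpatient$procedure_date,
                          admission_date = fx$inpatient$admission_date,
                          discharge_date = fx$inpatient$discharge_date),
           fx$outpatient)
  expect_equal(r$rules, "out_of_region")

  two <- dplyr::bind_rows(fx$inpatient,
                          make_inpatient(admission_date = as.Date("2018-05-01"),
                                         discharge_date = as.Date("2018-05-02"),
                                         procedure_date = as.Date("2018-05-01")))
  expect_equal(run(two, fx$outpatient)$rules, "multiple_surgeries")

  nopri <- fx$inpatient; nopri$priority <- NA_character_
  expect_equal(run(nopri, fx$outpatient)$rules, "missing_priority")

  no_biopsy <- fx$outpatient[!startsWith(fx$outpatient$tariff_code, "B-"), ]
  expect_equal(run(fx$inpatient, no_biopsy)$rules, "no_biopsy")

  no_imaging <- fx$outpatient[!startsWith(fx$outpatient$tariff_code, "M-"), ]
  expect_equal(run(fx$inpatient, no_imaging)$rules, "no_imaging")

  # last biopsy day 20, surgery day 386: gap 366 -> outlier; imaging kept in
  # window by moving the mammography to day 200
  late <- fx$inpatient
  late$procedure_date <- as.Date("2018-01-01") + 386
  late$admission_date <- late$procedure_date
  late$discharge_date <- late$procedure_date + 2
  outl <- fx$outpatient
  outl$service_date[outl$tariff_code == "M-MONO"] <- as.Date("2018-01-01") + 200
  expect_equal(run(late, outl)$rules, "over_365_days")
  # a gap of exactly 365 days is kept
  late$procedure_date <- as.Date("2018-01-01") + 385
  late$admission_date <- late$procedure_date
  late$discharge_date <- late$procedure_date + 2
  expect_equal(run(late, outl)$kept, 1L)

  # overlapping violations: residency outranks missing priority
  both <- nopri; both$resident_flag <- FALSE
  expect_equal(run(both, fx$outpatient)$rules, "out_of_region")
})

test_that("imaging lookback is closed on the right and open on the left", {
  fx <- clean_fixture()
  # surgery day 60: imaging on the surgery day counts
  op <- fx$outpatient
  op$service_date[op$tariff_code == "M-MONO"] <- as.Date("2018-01-01") + 60
  expect_equal(apply_exclusions(select_cases(fx$inpatient), op)$report$n_kept, 1L)
  # imaging exactly 365 days before surgery falls outside the window
  op$service_date[op$tariff_code == "M-MONO"] <- as.Date("2018-01-01") + 60 - 365
  res <- apply_exclusions(select_cases(fx$inpatient), op)
  expect_equal(unname(res$report$counts[["no_imaging"]]), 1L)
})

test_that("exclusion filtering is idempotent and monotone in the outlier threshold", {
  rec <- generate_cohort(one_hospital_config(
    80, seed = 41, rates = c(over_365_days = 0.3, no_imaging = 0.2)))
  cases0 <- select_cases(rec$inpatient)
  res <- apply_exclusions(cases0, rec$outpatient)
  again <- apply_exclusions(res$cases, rec$outpatient)
  expect_equal(again$report$n_kept, res$report$n_kept)
  expect_true(all(again$report$counts == 0L))

  kept_at <- vapply(c(200, 365, 500, 1000), function(thr) {
    apply_exclusions(cases0, rec$outpatient, max_gap_days = thr)$report$n_kept
  }, integer(1))
  expect_true(all(diff(kept_at) >= 0))
})

test_that("the event-log window runs from the last biopsy to surgery", {
  fx <- clean_fixture()
  res <- apply_exclusions(select_cases(fx$inpatient), fx$outpatient)
  log <- build_event_log(res$cases, fx$outpatient)
  # first biopsy (day 0) and the day-30 mammography... mammography is inside
  # the window [20, 60]; the day-0 biopsy is not
  expect_equal(log$activity, c("Biopsy", "Mammography", "Outpatient visit", "BCT"))
  expect_equal(as.integer(log$date - as.Date("2018-01-01")), c(20L, 30L, 40L, 60L))

  # no intermediate exams -> two-event trace
  op2 <- fx$outpatient[startsWith(fx$outpatient$tariff_code, "B-"), ]
  op2 <- dplyr::bind_rows(op2, outpatient_row("p1", 25, "U-MONO", 1.70))
  res2 <- apply_exclusions(select_cases(fx$inpatient), op2)
  log2 <- build_event_log(res2$cases,
                          op2[op2$service_date <= as.Date("2018-01-21"), ])
  expect_equal(log2$activity, c("Biopsy", "BCT"))
})

test_that("same-day events are ordered by the canonical activity order then tariff code", {
  fx <- clean_fixture()
  d <- as.Date("2018-01-21")  # same day as the last biopsy
  op <- dplyr::bind_rows(
    fx$outpatient,
    outpatient_row("p1", 20, "U-MONO", 1.70),
    outpatient_row("p1", 20, "M-BIL", 4.10),
    outpatient_row("p1", 20, "M-MONO", 2.36))
  res <- apply_exclusions(select_cases(fx$inpatient), op)
  log <- build_event_log(res$cases, op)
  day20 <- log[log$date == d, ]
  expect_equal(day20$activity,
               c("Biopsy", "Mammography", "Mammography", "Ultrasound"))
  expect_equal(day20$tariff_code[2:3], c("M-BIL", "M-MONO"))
})

test_that("total in-window event counts match an independent filter-and-count pass", {
  rec <- generate_cohort(one_hospital_config(100, seed = 43))
  ch <- build_cohort(rec)
  # brute force: one row per kept case's in-window outpatient services + 1 surgery
  df <- as.data.frame(rec$outpatient)
  known <- c("B-FNA", "B-ECR", "B-SMB", "B-SRA", "M-MONO", "M-BIL", "M-TOMO",
             "U-MONO", "U-BIL", "V-FIRST", "V-FUP")
  n_expect <- 0L
  for (i in seq_len(nrow(ch$cases))) {
    cs <- ch$cases[i, ]
    sub <- df[df$patient_id == cs$patient_id &
                df$service_date >= cs$last_biopsy_date &
                df$service_date <= cs$surgery_date &
                df$tariff_code %in% known, ]
    n_expect <- n_expect + nrow(sub) + 1L
  }
  expect_equal(nrow(ch$log), n_expect)
})

test_that("injected violations are attributed to exactly the injected rule", {
  rates <- c(out_of_region = 0.08, multiple_surgeries = 0.08,
             missing_priority = 0.08, no_biopsy = 0.08, no_imaging = 0.08,
             over_365_days = 0.08)
  rec <- generate_cohort(one_hospital_config(250, seed = 47, rates = rates))
  res <- apply_exclusions(select_cases(rec$inpatient), rec$outpatient)
  merged <- merge(as.data.frame(res$report$details), as.data.frame(rec$injections),
                  by = "patient_id", suffixes = c("_found", "_injected"))
  expect_equal(nrow(merged), 250L)
  expect_identical(merged$rule_found, merged$rule_injected)
  expect_equal(res$report$n_input,
               res$report$n_kept + sum(res$report$counts))
})
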