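#' Waiting-time distribution for one transition
#'
#' Day gaps between activities are modelled as log-normal, parameterized by
#' the target median (days) and a geometric standard deviation, then rounded
#' to whole days. The log-normal gives the right-skewed waiting times with
#' long upper tails characteristic of surgical pathways; the median
#' parameterization makes recovery checks direct (the median of a log-normal
#' is exactly the `median` argument).
#'
#' @param median_days target median gap in days (>= 0).
#' @param gsd geometric standard deviation (>= 1; 1 means a deterministic
#'   gap of `median_days`).
#' @return list with elements `median` and `gsd`.
#' @export
gap_dist <- function(median_days, gsd = 1.8) {
  if (!is.numeric(median_days) || median_days < 0) {
    abort("gap_dist: median_days must be >= 0")
  }
  if (!is.numeric(gsd) || gsd < 1) {
    abort("gap_dist: gsd must be >= 1")
  }
  list(median = as.numeric(median_days), gsd = as.numeric(gsd))
}

draw_gap <- function(dist) {
  if (dist$gsd == 1 || dist$median == 0) return(as.integer(round(dist$median)))
  as.integer(round(rlnorm(1L, meanlog = log(dist$median), sdlog = log(dist$gsd))))
}

default_gap_dists <- function() {
  list(
    "Biopsy->Biopsy"                     = gap_dist(20, 1.6),
    "Biopsy->Surgery"                    = gap_dist(45, 2.0),
    "Mammography->Outpatient visit"      = gap_dist(15, 2.0),
    "Outpatient visit->Outpatient visit" = gap_dist(15, 1.6),
    "Outpatient visit->Surgery"          = gap_dist(30, 1.8)
  )
}

#' Describe one hospital for the synthetic cohort generator
#'
#' A hospital profile fixes the number of patients treated, the mix of
#' pathway motifs, the transition waiting-time distributions, and the
#' surgery mix. Motifs emulate the recurrent patterns of real pathways:
#' a direct last-biopsy-to-surgery jump with no intervening exam, repeated
#' outpatient visits (a visit loop), a mammography + ultrasound same-day
#' cluster, and same-day exam repetition.
#'
#' @param hospital_id opaque hospital identifier.
#' @param n_patients nonnegative number of patients to generate.
#' @param motif_probs list with probabilities `direct_surgery`, `visit_loop`,
#'   `same_day_cluster`, `exam_repeat`, each in \[0, 1\].
#' @param gap_dists named list of [gap_dist()] objects keyed
#'   `"source->target"`; see [default_gap_dists] names for the transitions
#'   the generator draws from.
#' @param surgery_mix named probabilities over `BCT`, `mastectomy`,
#'   `reconstruction`; must sum to 1.
#' @return object of class `hospital_profile`.
#' @export
hospital_profile <- function(hospital_id,
                             n_patients,
                             motif_probs = list(direct_surgery = 0.08,
                                                visit_loop = 0.35,
                                                same_day_cluster = 0.45,
                                                exam_repeat = 0.10),
                             gap_dists = default_gap_dists(),
                             surgery_mix = c(BCT = 0.66, mastectomy = 0.24,
                                             reconstruction = 0.10)) {
  gd <- default_gap_dists()
  gd[names(gap_dists)] <- gap_dists
  prof <- structure(
    list(hospital_id = as.character(hospital_id),
         n_patients = as.integer(n_patients),
         motif_probs = motif_probs,
         gap_dists = gd,
         surgery_mix = surgery_mix),
    class = "hospital_profile")
  validate_hospital_profile(prof)
  prof
}

validate_hospital_profile <- function(prof) {
  id <- prof$hospital_id
  if (is.na(prof$n_patients) || prof$n_patients < 0) {
    abort(sprintf("hospital '%s': n_patients must be a nonnegative integer", id))
  }
  needed <- c("direct_surgery", "visit_loop", "same_day_cluster", "exam_repeat")
  for (m in needed) {
    p <- prof$motif_probs[[m]]
    if (is.null(p) || !is.numeric(p) || p < 0 || p > 1) {
      abort(sprintf("hospital '%s': motif_probs$%s must lie in [0, 1]", id, m))
    }
  }
  mix <- prof$surgery_mix
  if (!all(c("BCT", "mastectomy", "reconstruction") %in% names(mix)) ||
      any(mix < 0) || any(mix > 1)) {
    abort(sprintf(
      "hospital '%s': surgery_mix must be probabilities over BCT/mastectomy/reconstruction", id))
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    abort(sprintf("hospital '%s': surgery_mix must sum to 1", id))
  }
  for (nm in names(prof$gap_dists)) {
    d <- prof$gap_dists[[nm]]
    if (!is.numeric(d$median) || d$median < 0 || !is.numeric(d$gsd) || d$gsd < 1) {
      abort(sprintf("hospital '%s': gap_dists[['%s']] must have median >= 0 and gsd >= 1",
                    id, nm))
    }
  }
  invisible(prof)
}

#' Configuration for the synthetic cohort generator
#'
#' @param hospitals list of [hospital_profile()] objects (at least one).
#' @param catalog a [default_catalog()]-style tariff catalog.
#' @param exclusion_injection_rates named rates in \[0, 1\] for the six
#'   exclusion rules (`out_of_region`, `multiple_surgeries`,
#'   `missing_priority`, `no_biopsy`, `no_imaging`, `over_365_days`).
#'   A flagged patient is an otherwise-clean patient mutated so that it
#'   violates exactly that rule. Unnamed rules default to 0.
#' @param date_origin first calendar day of the generated study year.
#' @param seed integer seed; identical configurations produce byte-identical
#'   record streams.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(hospitals,
                             catalog = default_catalog(),
                             exclusion_injection_rates = NULL,
                             date_origin = as.Date("2018-01-01"),
                             seed = 1L) {
  rates <- setNames(rep(0, length(exclusion_rule_ids())), exclusion_rule_ids())
  if (!is.null(exclusion_injection_rates)) {
    unknown <- setdiff(names(exclusion_injection_rates), exclusion_rule_ids())
    if (length(unknown)) {
      abort(paste0("generator_config: unknown exclusion rule(s): ",
                   paste(unknown, collapse = ", ")))
    }
    rates[names(exclusion_injection_rates)] <- exclusion_injection_rates
  }
  cfg <- structure(
    list(hospitals = hospitals, catalog = catalog,
         exclusion_injection_rates = rates,
         date_origin = as.Date(date_origin), seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (length(cfg$hospitals) < 1) {
    abort("generator_config: hospitals must contain at least one profile")
  }
  for (h in cfg$hospitals) validate_hospital_profile(h)
  r <- cfg$exclusion_injection_rates
  if (any(r < 0) || any(r > 1)) {
    bad <- names(r)[r < 0 | r > 1][1]
    abort(sprintf("generator_config: exclusion_injection_rates$%s must lie in [0, 1]", bad))
  }
  if (is.na(cfg$seed)) abort("generator_config: seed must be an integer")
  invisible(cfg)
}

#' Four-hospital demonstration configuration
#'
#' Heterogeneous volumes (about a tenth of the volumes of the four hospitals
#' profiled in the study region), with per-hospital motif and waiting-time
#' settings: two high-volume hospitals (one with a sizeable fraction of
#' direct biopsy-to-surgery cases, one dominated by repeated visits), one
#' medium and one small hospital where direct cases wait longest.
#'
#' @param seed integer seed.
#' @return a [generator_config()].
#' @export
demo_config <- function(seed = 42L) {
  hospitals <- list(
    hospital_profile("HOSP-A", 260,
      motif_probs = list(direct_surgery = 0.21, visit_loop = 0.30,
                         same_day_cluster = 0.50, exam_repeat = 0.07),
      gap_dists = list("Biopsy->Surgery" = gap_dist(43, 2.2),
                       "Mammography->Outpatient visit" = gap_dist(23, 2.2),
                       "Outpatient visit->Outpatient visit" = gap_dist(14, 1.6),
                       "Outpatient visit->Surgery" = gap_dist(25, 2.0))),
    hospital_profile("HOSP-B", 250,
      motif_probs = list(direct_surgery = 0.02, visit_loop = 0.62,
                         same_day_cluster = 0.31, exam_repeat = 0.12),
      gap_dists = list("Mammography->Outpatient visit" = gap_dist(15, 1.8),
                       "Outpatient visit->Outpatient visit" = gap_dist(15, 1.6),
                       "Outpatient visit->Surgery" = gap_dist(28, 1.8)),
      surgery_mix = c(BCT = 0.60, mastectomy = 0.30, reconstruction = 0.10)),
    hospital_profile("HOSP-C", 110,
      motif_probs = list(direct_surgery = 0.03, visit_loop = 0.50,
                         same_day_cluster = 0.45, exam_repeat = 0.08),
      gap_dists = list("Outpatient visit->Outpatient visit" = gap_dist(16, 1.5),
                       "Outpatient visit->Surgery" = gap_dist(24, 1.6)),
      surgery_mix = c(BCT = 0.78, mastectomy = 0.16, reconstruction = 0.06)),
    hospital_profile("HOSP-D", 45,
      motif_probs = list(direct_surgery = 0.22, visit_loop = 0.35,
                         same_day_cluster = 0.40, exam_repeat = 0.05),
      gap_dists = list("Biopsy->Surgery" = gap_dist(62, 1.6),
                       "Outpatient visit->Surgery" = gap_dist(50, 1.7)),
      surgery_mix = c(BCT = 0.55, mastectomy = 0.30, reconstruction = 0.15))
  )
  generator_config(hospitals, seed = seed)
}

#' Generate one patient's dated activity sequence
#'
#' Draws one pathway trace for a patient of the given hospital, using the
#' current RNG state (seed upstream, e.g. via [generate_cohort()] or
#' `withr::with_seed`). Every trace begins with a biopsy on day 0, carries a
#' same-day mammography (so the imaging requirement is satisfiable by
#' construction), and ends with exactly one surgery drawn from the hospital's
#' surgery mix. Motifs are superimposed per the profile probabilities; with
#' the direct-surgery motif a second (final) biopsy is followed immediately
#' by surgery with no exam in between.
#'
#' @param profile a [hospital_profile()].
#' @param catalog a tariff catalog.
#' @return tibble with columns `day` (integer offset from the trace start),
#'   `activity`, `tariff_code`, `cost`; rows in chronological order with
#'   same-day ties in the canonical activity order.
#' @export
generate_trace <- function(profile, catalog = default_catalog()) {
  p <- profile$motif_probs
  gd <- profile$gap_dists
  days <- integer(0); acts <- character(0)
  codes <- character(0); costs <- numeric(0)
  add <- function(day, activity, category = NULL) {
    days <<- c(days, as.integer(day)); acts <<- c(acts, activity)
    if (is.null(category)) {
      codes <<- c(codes, NA_character_); costs <<- c(costs, NA_real_)
    } else {
      t <- sample_tariff(catalog, category)
      codes <<- c(codes, t$tariff_code); costs <<- c(costs, t$cost)
    }
  }

  add(0L, "Biopsy", "biopsy")
  add(0L, "Mammography", "mammography")
  if (runif(1) < p$exam_repeat) add(0L, "Mammography", "mammography")
  if (runif(1) < p$same_day_cluster) add(0L, "Ultrasound", "ultrasound")

  stype <- sample(c("BCT", "mastectomy", "reconstruction"), 1L,
                  prob = profile$surgery_mix[c("BCT", "mastectomy", "reconstruction")])
  if (runif(1) < p$direct_surgery) {
    # second, final biopsy strictly after the imaging day, then surgery with
    # nothing in between
    d1 <- max(1L, draw_gap(gd[["Biopsy->Biopsy"]]))
    add(d1, "Biopsy", "biopsy")
    s_day <- d1 + draw_gap(gd[["Biopsy->Surgery"]])
  } else {
    v1 <- draw_gap(gd[["Mammography->Outpatient visit"]])
    add(v1, "Outpatient visit", "visit")
    last <- v1
    if (runif(1) < p$visit_loop) {
      last <- last + draw_gap(gd[["Outpatient visit->Outpatient visit"]])
      add(last, "Outpatient visit", "visit")
    }
    s_day <- last + draw_gap(gd[["Outpatient visit->Surgery"]])
  }
  add(s_day, surgery_type_label(stype))

  ord <- order(days, activity_rank(acts), codes, method = "radix")
  tibble(day = days[ord], activity = acts[ord],
         tariff_code = codes[ord], cost = costs[ord])
}

#' Generate a synthetic inpatient/outpatient cohort
#'
#' Produces the two administrative record streams the pipeline consumes,
#' plus an injection ledger recording which exclusion rule (if any) each
#' patient was mutated to violate. Clean patients have exactly one
#' qualifying surgery admission, at least one biopsy before surgery, at
#' least one mammography or ultrasound within 365 days before surgery, a
#' priority class, in-region residence, and a last-biopsy-to-surgery gap of
#' at most 365 days. A patient flagged for a rule violates exactly that rule
#' and no earlier one in the evaluation order, which makes exclusion counts
#' attributable in tests.
#'
#' Outpatient service dates are whole calendar days: the source systems do
#' not record the time of day.
#'
#' @param config a [generator_config()].
#' @return list with tibbles `inpatient` (patient_id, hospital_id,
#'   admission_date, discharge_date, principal_dx, secondary_dx,
#'   procedure_code, procedure_date, priority, resident_flag), `outpatient`
#'   (patient_id, provider_id, service_date, tariff_code, cost) and
#'   `injections` (patient_id, hospital_id, rule; rule is NA for clean
#'   patients).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  catalog <- config$catalog
  rates <- config$exclusion_injection_rates

  withr::with_seed(config$seed, {
    inp <- list(); outp <- list(); inj <- list()
    k <- 0L
    for (prof in config$hospitals) {
      if (prof$n_patients == 0L) next
      for (i in seq_len(prof$n_patients)) {
        k <- k + 1L
        pid <- sprintf("%s-%04d", prof$hospital_id, i)
        tr <- generate_trace(prof, catalog)
        anchor <- config$date_origin + (sample.int(330L, 1L) - 1L)

        rule <- NA_character_
        for (r in exclusion_rule_ids()) {
          if (rates[[r]] > 0 && runif(1) < rates[[r]]) { rule <- r; break }
        }

        s_idx <- which(tr$activity %in% surgery_labels())
        s_off <- tr$day[s_idx]
        stype <- tr$activity[s_idx]
        last_biopsy_off <- max(tr$day[tr$activity == "Biopsy"])

        if (!is.na(rule) && rule == "over_365_days") {
          # push surgery past the 365-day outlier threshold, but add one
          # imaging service inside the lookback window so only this rule fires
          s_off <- last_biopsy_off + 366L + sample.int(30L, 1L)
          m <- sample_tariff(catalog, "mammography")
          tr <- bind_rows(
            tr[-s_idx, ],
            tibble(day = s_off - sample.int(364L, 1L), activity = "Mammography",
                   tariff_code = m$tariff_code, cost = m$cost),
            tibble(day = s_off, activity = stype,
                   tariff_code = NA_character_, cost = NA_real_))
          s_idx <- which(tr$activity %in% surgery_labels())
        }

        op_rows <- tr[-s_idx, ]
        if (!is.na(rule) && rule == "no_biopsy") {
          op_rows <- op_rows[op_rows$activity != "Biopsy", ]
        }
        if (!is.na(rule) && rule == "no_imaging") {
          op_rows <- op_rows[!op_rows$activity %in% c("Mammography", "Ultrasound"), ]
        }

        # diagnosis coding: mostly a 174.x principal, some in-situ 233.0,
        # occasionally the breast code in secondary position
        u <- runif(1)
        if (u < 0.72) {
          principal <- sample(c("174.1", "174.4", "174.8", "174.9"), 1L)
          secondary <- NA_character_
        } else if (u < 0.88) {
          principal <- "233.0"; secondary <- NA_character_
        } else {
          principal <- "401.9"
          secondary <- sample(c("174.9", "233.0"), 1L)
        }
        surgery_type_key <- c(BCT = "BCT", Mastectomy = "mastectomy",
                              Reconstruction = "reconstruction")[[stype]]
        pcode <- catalog$surgery_codes$procedure_code[
          catalog$surgery_codes$surgery_type == surgery_type_key]
        pcode <- pcode[sample.int(length(pcode), 1L)]

        priority <- if (!is.na(rule) && rule == "missing_priority") NA_character_ else "P1"
        resident <- is.na(rule) || rule != "out_of_region"

        s_date <- anchor + s_off
        inp_pat <- tibble(
          patient_id = pid, hospital_id = prof$hospital_id,
          admission_date = s_date,
          discharge_date = s_date + sample.int(4L, 1L),
          principal_dx = principal, secondary_dx = secondary,
          procedure_code = pcode, procedure_date = s_date,
          priority = priority, resident_flag = resident)
        if (!is.na(rule) && rule == "multiple_surgeries") {
          s2 <- s_date + 30L + sample.int(60L, 1L)
          inp_pat <- bind_rows(inp_pat, tibble(
            patient_id = pid, hospital_id = prof$hospital_id,
            admission_date = s2, discharge_date = s2 + sample.int(4L, 1L),
            principal_dx = principal, secondary_dx = secondary,
            procedure_code = pcode, procedure_date = s2,
            priority = priority, resident_flag = resident))
        }
        inp[[k]] <- inp_pat
        outp[[k]] <- tibble(
          patient_id = pid, provider_id = prof$hospital_id,
          service_date = anchor + op_rows$day,
          tariff_code = op_rows$tariff_code, cost = op_rows$cost)
        inj[[k]] <- tibble(patient_id = pid, hospital_id = prof$hospital_id,
                           rule = rule)
      }
    }
    empty_inp <- tibble(patient_id = character(), hospital_id = character(),
                        admission_date = as.Date(character()),
                        discharge_date = as.Date(character()),
                        principal_dx = character(), secondary_dx = character(),
                        procedure_code = character(),
                        procedure_date = as.Date(character()),
                        priority = character(), resident_flag = logical())
    empty_out <- tibble(patient_id = character(), provider_id = character(),
                        service_date = as.Date(character()),
                        tariff_code = character(), cost = numeric())
    list(inpatient = if (k) bind_rows(inp) else empty_inp,
         outpatient = if (k) bind_rows(outp) else empty_out,
         injections = if (k) bind_rows(inj) else
           tibble(patient_id = character(), hospital_id = character(),
                  rule = character()))
  })
}

#' Write / read the raw record streams as CSV
#'
#' Dates are written ISO 8601 (YYYY-MM-DD).
#'
#' @param records list with `inpatient` and `outpatient` tibbles as returned
#'   by [generate_cohort()].
#' @param inpatient_path,outpatient_path file paths.
#' @return `write_records_csv` returns the paths invisibly;
#'   `read_records_csv` returns a list with `inpatient` and `outpatient`.
#' @export
write_records_csv <- function(records, inpatient_path, outpatient_path) {
  readr::write_csv(records$inpatient, inpatient_path, na = "")
  readr::write_csv(records$outpatient, outpatient_path, na = "")
  invisible(c(inpatient = inpatient_path, outpatient = outpatient_path))
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(inpatient_path, outpatient_path) {
  inp <- readr::read_csv(
    inpatient_path,
    col_types = readr::cols(
      patient_id = "c", hospital_id = "c", admission_date = "D",
      discharge_date = "D", principal_dx = "c", secondary_dx = "c",
      procedure_code = "c", procedure_date = "D", priority = "c",
      resident_flag = "l"))
  outp <- readr::read_csv(
    outpatient_path,
    col_types = readr::cols(patient_id = "c", provider_id = "c",
                            service_date = "D", tariff_code = "c",
                            cost = "d"))
  list(inpatient = inp, outpatient = outp)
}

#' Read / write a generator configuration as YAML
#'
#' The YAML mirrors the [generator_config()] fields: `seed`, `date_origin`,
#' `exclusion_injection_rates`, and a `hospitals` list whose entries carry
#' `hospital_id`, `n_patients`, `motif_probs`, `surgery_mix` and `gap_dists`
#' (each gap distribution as `median` and `gsd` keyed by
#' `"source->target"`). The tariff catalog is not serialized; the default
#' catalog (optionally rescaled) is attached on read.
#'
#' @param path YAML file path.
#' @param catalog catalog to attach on read.
#' @param config a `generator_config` to serialize.
#' @return `read_generator_config` returns a [generator_config()].
#' @export
read_generator_config <- function(path, catalog = default_catalog()) {
  y <- yaml::read_yaml(path)
  hospitals <- lapply(y$hospitals, function(h) {
    gd <- lapply(h$gap_dists, function(d) gap_dist(d$median, d$gsd))
    hospital_profile(h$hospital_id, h$n_patients,
                     motif_probs = h$motif_probs,
                     gap_dists = gd,
                     surgery_mix = unlist(h$surgery_mix))
  })
  generator_config(hospitals, catalog = catalog,
                   exclusion_injection_rates = unlist(y$exclusion_injection_rates),
                   date_origin = as.Date(y$date_origin %||% "2018-01-01"),
                   seed = y$seed %||% 1L)
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  y <- list(
    seed = config$seed,
    date_origin = format(config$date_origin),
    exclusion_injection_rates = as.list(config$exclusion_injection_rates),
    hospitals = lapply(config$hospitals, function(h) {
      list(hospital_id = h$hospital_id, n_patients = h$n_patients,
           motif_probs = h$motif_probs,
           surgery_mix = as.list(h$surgery_mix),
           gap_dists = lapply(h$gap_dists, function(d)
             list(median = d$median, gsd = d$gsd)))
    }))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
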