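# Independent reference implementations used as oracles. Deliberately
# written in plain base R with explicit loops, sharing no code with the
# package internals.

get0n <- function(lst, k) if (is.null(lst[[k]])) 0L else lst[[k]]

# Brute-force directly-follows counter: walks every trace with a for-loop.
oracle_map <- function(log) {
  df <- as.data.frame(log)
  cases <- unique(df$case_id)
  act_events <- list(); act_cases <- list()
  edge_occ <- list(); edge_cases <- list(); edge_gaps <- list()
  starts <- list(); ends <- list()
  for (cid in cases) {
    sub <- df[df$case_id == cid, ]
    acts <- sub$activity
    starts[[acts[1]]] <- get0n(starts, acts[1]) + 1L
    last <- acts[length(acts)]
    ends[[last]] <- get0n(ends, last) + 1L
    for (a in acts) act_events[[a]] <- get0n(act_events, a) + 1L
    for (a in unique(acts)) act_cases[[a]] <- get0n(act_cases, a) + 1L
    if (length(acts) >= 2) {
      seen <- character(0)
      for (i in seq_len(length(acts) - 1)) {
        k <- paste(acts[i], acts[i + 1], sep = "|")
        edge_occ[[k]] <- get0n(edge_occ, k) + 1L
        edge_gaps[[k]] <- c(edge_gaps[[k]],
                            as.integer(sub$date[i + 1] - sub$date[i]))
        if (!(k %in% seen)) {
          edge_cases[[k]] <- get0n(edge_cases, k) + 1L
          seen <- c(seen, k)
        }
      }
    }
  }
  list(n_cases = length(cases), act_events = act_events,
       act_cases = act_cases, edge_occ = edge_occ, edge_cases = edge_cases,
       edge_gaps = edge_gaps, starts = starts, ends = ends)
}

# Exhaustive path-existence check: does `a` lie on some start-to-end path of
# the map (dashed markers as endpoints)? Recursive DFS, all simple paths.
oracle_on_path <- function(map, a) {
  src <- map$edges$source; tgt <- map$edges$target
  to_end <- function(x, visited) {
    if (x %in% map$end_edges$activity) return(TRUE)
    for (y in unique(tgt[src == x])) {
      if (!(y %in% visited) && to_end(y, c(visited, y))) return(TRUE)
    }
    FALSE
  }
  from_start <- function(x, visited) {
    if (x %in% map$start_edges$activity) return(TRUE)
    for (y in unique(src[tgt == x])) {
      if (!(y %in% visited) && from_start(y, c(visited, y))) return(TRUE)
    }
    FALSE
  }
  from_start(a, a) && to_end(a, a)
}

# Random small event logs for property tests (call under a fixed seed).
random_log <- function(n_cases = sample(1:10, 1), max_events = 8) {
  pool <- c("Biopsy", "Mammography", "Ultrasound", "Outpatient visit", "BCT")
  rows <- lapply(seq_len(n_cases), function(i) {
    k <- sample(seq_len(max_events), 1)
    days <- cumsum(c(0L, sample(0:9, max(k - 1, 0), replace = TRUE)))
    tibble::tibble(
      case_id = sprintf("c%02d", i),
      activity = sample(pool, k, replace = TRUE),
      date = as.Date("2018-03-01") + days,
      hospital_id = "X", tariff_code = NA_character_, cost = NA_real_)
  })
  as_event_log(dplyr::bind_rows(rows))
}

# Hand-built event log from a compact spec: list of character vectors
# "activity@day" per case. Tariff codes are attached by activity so costs
# stay consistent with the default catalog.
tiny_log <- function(...) {
  traces <- list(...)
  code_of <- c(Biopsy = "B-FNA", Mammography = "M-MONO",
               Ultrasound = "U-MONO", "Outpatient visit" = "V-FIRST")
  cost_of <- c("B-FNA" = 0.71, "M-MONO" = 2.36, "U-MONO" = 1.70,
               "V-FIRST" = 5.43)
  rows <- lapply(seq_along(traces), function(i) {
    parts <- strsplit(traces[[i]], "@", fixed = TRUE)
    act <- vapply(parts, `[`, "", 1)
    day <- as.integer(vapply(parts, `[`, "", 2))
    code <- unname(code_of[act])
    tibble::tibble(case_id = sprintf("t%02d", i), activity = act,
                   date = as.Date("2018-02-01") + day, hospital_id = "X",
                   tariff_code = code, cost = unname(cost_of[code]))
  })
  as_event_log(dplyr::bind_rows(rows))
}

# Single-hospital generator config used across tests.
one_hospital_config <- function(n, seed, motif_probs = NULL, gap_dists = NULL,
                                rates = NULL) {
  mp <- list(direct_surgery = 0.1, visit_loop = 0.3, same_day_cluster = 0.4,
             exam_repeat = 0.1)
  if (!is.null(motif_probs)) mp[names(motif_probs)] <- motif_probs
  prof <- hospital_profile("HX", n, motif_probs = mp,
                           gap_dists = gap_dists %||% list())
  generator_config(list(prof), exclusion_injection_rates = rates, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convenience: raw records -> filtered cases + event log.
build_cohort <- function(records, catalog = default_catalog()) {
  cases0 <- select_cases(records$inpatient)
  res <- apply_exclusions(cases0, records$outpatient, catalog)
  list(cases = res$cases, report = res$report,
       log = build_event_log(res$cases, records$outpatient, catalog))
}
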