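#' Mine a directly-follows process map from an event log
#'
#' An edge `A -> B` exists when at least one case performs `B` immediately
#' after `A` with no intermediate activity. Each edge collects the multiset
#' of day gaps between its endpoint events, the total number of
#' directly-follows occurrences (self-loops included, so repeated exams are
#' visible), and its case coverage (how many cases contain the transition at
#' least once). The first and last activity of every case feed the dashed
#' start/end markers, so start and end case counts both sum to the number of
#' cases.
#'
#' @param log an event log (tibble with `case_id`, `activity`, `date`).
#' @return object of class `process_map`: list with
#'   \describe{
#'     \item{activities}{tibble `activity`, `n_events`, `n_cases`,
#'       `coverage_pct`}
#'     \item{edges}{tibble `source`, `target`, `occurrences`, `n_cases`,
#'       `coverage_pct`, `gaps` (list of integer day-gap vectors)}
#'     \item{start_edges, end_edges}{tibbles `activity`, `n_cases`}
#'     \item{n_cases}{number of cases in the log}
#'   }
#' @export
mine_map <- function(log) {
  ev <- as_tibble(log)
  if (nrow(ev) == 0) abort("mine_map: the event log is empty")
  n_cases <- dplyr::n_distinct(ev$case_id)

  activities <- ev %>%
    group_by(activity = .data$activity) %>%
    summarise(n_events = n(), n_cases = n_distinct(.data$case_id),
              .groups = "drop") %>%
    mutate(coverage_pct = 100 * .data$n_cases / !!n_cases) %>%
    arrange(.data$activity)

  pairs <- ev %>%
    group_by(.data$case_id) %>%
    mutate(target = lead(.data$activity),
           gap = as.integer(lead(.data$date) - .data$date)) %>%
    ungroup() %>%
    filter(!is.na(.data$target))
  if (any(pairs$gap < 0)) {
    abort("mine_map: negative day gap; events are not chronologically ordered")
  }

  edges <- pairs %>%
    group_by(source = .data$activity, target = .data$target) %>%
    summarise(occurrences = n(), n_cases = n_distinct(.data$case_id),
              gaps = list(.data$gap), .groups = "drop") %>%
    mutate(coverage_pct = 100 * .data$n_cases / !!n_cases) %>%
    select("source", "target", "occurrences", "n_cases", "coverage_pct",
           "gaps") %>%
    arrange(.data$source, .data$target)

  ends <- ev %>%
    group_by(.data$case_id) %>%
    summarise(first = dplyr::first(.data$activity),
              last = dplyr::last(.data$activity), .groups = "drop")
  start_edges <- ends %>% count(activity = .data$first, name = "n_cases") %>%
    arrange(.data$activity)
  end_edges <- ends %>% count(activity = .data$last, name = "n_cases") %>%
    arrange(.data$activity)

  structure(list(activities = activities, edges = edges,
                 start_edges = start_edges, end_edges = end_edges,
                 n_cases = n_cases),
            class = "process_map")
}

#' @export
print.process_map <- function(x, ...) {
  cat("<process_map> ", nrow(x$activities), " activities, ", nrow(x$edges),
      " directly-follows edges, ", x$n_cases, " cases\n", sep = "")
  invisible(x)
}

#' Performance statistic of one directly-follows edge
#'
#' Computes the median (default), mean, or total of the day-gap multiset of
#' an edge. The median of an even-sized multiset is the arithmetic mean of
#' the two central values. A value of 0 days is the "instant" case: source
#' and target completed on the same day.
#'
#' @param map a [mine_map()] result.
#' @param source,target edge endpoints.
#' @param statistic one of `"median"`, `"mean"`, `"total"`.
#' @return the statistic, in days.
#' @export
edge_statistic <- function(map, source, target,
                           statistic = c("median", "mean", "total")) {
  statistic <- match.arg(statistic)
  i <- which(map$edges$source == source & map$edges$target == target)
  if (length(i) != 1) {
    abort(sprintf("edge_statistic: no edge %s -> %s in the map", source, target))
  }
  g <- map$edges$gaps[[i]]
  switch(statistic,
         median = stats::median(g),
         mean = mean(g),
         total = sum(g))
}

# --- importance zoom -------------------------------------------------------

# activities reachable from the artificial start marker following kept edges
reachable_from_start <- function(acts, edges, start_acts) {
  visited <- intersect(start_acts, acts)
  repeat {
    nxt <- unique(edges$target[edges$source %in% visited])
    nxt <- setdiff(intersect(nxt, acts), visited)
    if (!length(nxt)) break
    visited <- c(visited, nxt)
  }
  visited
}

reaches_end <- function(acts, edges, end_acts) {
  visited <- intersect(end_acts, acts)
  repeat {
    prv <- unique(edges$source[edges$target %in% visited])
    prv <- setdiff(intersect(prv, acts), visited)
    if (!length(prv)) break
    visited <- c(visited, prv)
  }
  visited
}

# disconnection score: a kept activity contributes one point for being
# unreachable from start and one for not reaching end
disconnection_score <- function(acts, edges, start_acts, end_acts) {
  fwd <- reachable_from_start(acts, edges, start_acts)
  bwd <- reaches_end(acts, edges, end_acts)
  (length(acts) - length(fwd)) + (length(acts) - length(bwd))
}

#' Importance zoom: keep the most important activities and paths
#'
#' Reduces a map to its most important elements while guaranteeing that no
#' depicted activity is disconnected. Three steps:
#'
#' 1. *Activity step*: rank activities by case coverage (descending, ties by
#'    label) and keep the top `ceiling(activity_zoom * n)`.
#' 2. *Path step*: among edges whose endpoints are both kept, rank by
#'    occurrences (descending, ties by source then target label) and keep
#'    the top `ceiling(path_zoom * m)`.
#' 3. *Repair step*: while any kept activity is unreachable from the
#'    artificial start marker or cannot reach the artificial end marker
#'    within the kept edges (start/end markers count as connectors), add
#'    back the highest-ranked dropped edge that strictly reduces the
#'    disconnection score. When no candidate edge can reconnect an activity
#'    (possible only when the activity step has removed all of its
#'    neighbours), the still-disconnected activities are pruned instead, so
#'    the guarantee that no depicted activity is disconnected is absolute.
#'    The result is always a sub-map of the input; no new elements are
#'    created.
#'
#' With both fractions at 1 the zoom is the identity.
#'
#' @param map a [mine_map()] result.
#' @param path_zoom fraction of paths to keep, in \[0, 1\] (default 0.8, a
#'   good trade-off between completeness and interpretability).
#' @param activity_zoom fraction of activities to keep, in \[0, 1\].
#' @return a `process_map` restricted to the kept elements; start/end
#'   markers are restricted to kept activities.
#' @export
zoom_map <- function(map, path_zoom = 0.8, activity_zoom = 1.0) {
  if (path_zoom < 0 || path_zoom > 1 || activity_zoom < 0 || activity_zoom > 1) {
    abort("zoom_map: zoom fractions must lie in [0, 1]")
  }
  acts <- map$activities
  ord_a <- order(-acts$n_cases, acts$activity, method = "radix")
  n_keep_a <- ceiling(activity_zoom * nrow(acts))
  kept_acts <- acts$activity[ord_a][seq_len(n_keep_a)]

  cand <- map$edges %>%
    filter(.data$source %in% kept_acts, .data$target %in% kept_acts)
  ord_e <- order(-cand$occurrences, cand$source, cand$target, method = "radix")
  cand <- cand[ord_e, ]
  n_keep_e <- ceiling(path_zoom * nrow(cand))
  kept <- cand[seq_len(n_keep_e), , drop = FALSE]
  dropped <- cand[-seq_len(n_keep_e), , drop = FALSE]

  start_acts <- intersect(map$start_edges$activity, kept_acts)
  end_acts <- intersect(map$end_edges$activity, kept_acts)

  repeat {
    score <- disconnection_score(kept_acts, kept, start_acts, end_acts)
    if (score == 0 || nrow(dropped) == 0) break
    improved <- FALSE
    for (i in seq_len(nrow(dropped))) {
      trial <- bind_rows(kept, dropped[i, ])
      if (disconnection_score(kept_acts, trial, start_acts, end_acts) < score) {
        kept <- trial
        dropped <- dropped[-i, , drop = FALSE]
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }

  # prune activities no candidate edge can reconnect (their neighbours were
  # removed by the activity step), cascading until the sub-map is clean
  repeat {
    fwd <- reachable_from_start(kept_acts, kept, start_acts)
    bwd <- reaches_end(kept_acts, kept, end_acts)
    disc <- setdiff(kept_acts, intersect(fwd, bwd))
    if (!length(disc)) break
    kept_acts <- setdiff(kept_acts, disc)
    kept <- kept %>%
      filter(.data$source %in% kept_acts, .data$target %in% kept_acts)
    start_acts <- intersect(start_acts, kept_acts)
    end_acts <- intersect(end_acts, kept_acts)
  }

  key <- paste(kept$source, kept$target, sep = "\r")
  edges_out <- map$edges %>%
    filter(paste(.data$source, .data$target, sep = "\r") %in% key)
  structure(
    list(activities = acts %>% filter(.data$activity %in% kept_acts),
         edges = edges_out,
         start_edges = map$start_edges %>% filter(.data$activity %in% kept_acts),
         end_edges = map$end_edges %>% filter(.data$activity %in% kept_acts),
         n_cases = map$n_cases),
    class = "process_map")
}

# --- rendering -------------------------------------------------------------

#' View configuration for map rendering
#'
#' @param primary_view `"frequency"` (case-coverage labels) or
#'   `"performance"` (elapsed-time labels).
#' @param statistic performance statistic: `"median"` (default; robust to
#'   the long upper tails of waiting times), `"mean"`, or `"total"`.
#' @param mixed add the other view's value as a secondary label in a
#'   smaller font.
#' @param percentage label frequencies as case-coverage percentages
#'   (default; comparable across hospitals of heterogeneous volume) rather
#'   than absolute occurrence counts.
#' @param path_zoom,activity_zoom importance-zoom fractions applied by
#'   [run_pipeline()] before rendering.
#' @return a list of class `view_config`.
#' @export
view_config <- function(primary_view = c("frequency", "performance"),
                        statistic = c("median", "mean", "total"),
                        mixed = TRUE, percentage = TRUE,
                        path_zoom = 0.8, activity_zoom = 1.0) {
  primary_view <- match.arg(primary_view)
  statistic <- match.arg(statistic)
  if (path_zoom < 0 || path_zoom > 1 || activity_zoom < 0 || activity_zoom > 1) {
    abort("view_config: zoom fractions must lie in [0, 1]")
  }
  structure(list(primary_view = primary_view, statistic = statistic,
                 mixed = mixed, percentage = percentage,
                 path_zoom = path_zoom, activity_zoom = activity_zoom),
            class = "view_config")
}

fmt_pct <- function(p) paste0(trimws(formatC(p, format = "fg", digits = 3)), "%")

fmt_days <- function(d) {
  if (d == 0) "instant"
  else paste0(trimws(formatC(d, format = "fg", digits = 3)), " d")
}

#' Render a process map as DOT text
#'
#' One box per activity labelled with its name and case coverage; solid
#' arrows for directly-follows edges labelled with the primary-view value
#' (and, in the mixed view, the secondary value in a smaller font); dashed
#' arrows from the start marker and to the end marker. Same-day transitions
#' are labelled "instant". Arrow pen widths scale monotonically with the
#' primary weight, and node fill intensity with case coverage. The output
#' parses with standard Graphviz layout tools.
#'
#' @param map a [mine_map()] (possibly zoomed) result.
#' @param view a [view_config()].
#' @return a single string of DOT source.
#' @export
render_dot <- function(map, view = view_config()) {
  ramp <- grDevices::colorRampPalette(c("#f7fbff", "#2171b5"))(101)
  edge_stat <- vapply(map$edges$gaps, function(g)
    switch(view$statistic, median = stats::median(g), mean = mean(g),
           total = sum(g)), numeric(1))
  freq_lab <- if (view$percentage) vapply(map$edges$coverage_pct, fmt_pct, "")
              else formatC(map$edges$occurrences, format = "d")
  perf_lab <- vapply(edge_stat, fmt_days, "")
  if (view$primary_view == "frequency") {
    primary <- freq_lab; secondary <- perf_lab
    weight <- if (view$percentage) map$edges$coverage_pct else map$edges$occurrences
  } else {
    primary <- perf_lab; secondary <- freq_lab
    weight <- edge_stat
  }
  penwidth <- if (nrow(map$edges) == 0) numeric(0)
    else if (diff(range(weight)) == 0) rep(2.5, length(weight))
    else 1 + 4 * (weight - min(weight)) / diff(range(weight))

  lines <- c(
    "digraph process_map {",
    "  rankdir=TB;",
    "  node [shape=box, style=\"rounded,filled\", fontname=\"Helvetica\"];",
    "  edge [fontname=\"Helvetica\"];",
    "  \"__start\" [shape=circle, label=\"\", width=0.25, fillcolor=\"#333333\"];",
    "  \"__end\" [shape=doublecircle, label=\"\", width=0.2, fillcolor=\"#333333\"];")
  for (i in seq_len(nrow(map$activities))) {
    a <- map$activities[i, ]
    lines <- c(lines, sprintf(
      "  \"%s\" [label=<%s<BR/>%s>, fillcolor=\"%s\"];",
      a$activity, a$activity, fmt_pct(a$coverage_pct),
      ramp[round(a$coverage_pct) + 1]))
  }
  for (i in seq_len(nrow(map$edges))) {
    e <- map$edges[i, ]
    lab <- if (isTRUE(view$mixed)) {
      sprintf("<%s<BR/><FONT POINT-SIZE=\"9\">%s</FONT>>", primary[i], secondary[i])
    } else {
      sprintf("<%s>", primary[i])
    }
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=%s, penwidth=%.3f];",
      e$source, e$target, lab, penwidth[i]))
  }
  for (i in seq_len(nrow(map$start_edges))) {
    s <- map$start_edges[i, ]
    lines <- c(lines, sprintf(
      "  \"__start\" -> \"%s\" [style=dashed, label=\"%d\"];",
      s$activity, s$n_cases))
  }
  for (i in seq_len(nrow(map$end_edges))) {
    s <- map$end_edges[i, ]
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"__end\" [style=dashed, label=\"%d\"];",
      s$activity, s$n_cases))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Serialize a process map to JSON
#'
#' @param map a [mine_map()] result.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
map_to_json <- function(map, path = NULL) {
  x <- list(
    n_cases = map$n_cases,
    activities = map$activities,
    edges = map$edges,
    start_edges = map$start_edges,
    end_edges = map$end_edges)
  js <- jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Two-patient illustrative event log
#'
#' A minimal log of two hypothetical patients, useful for demonstrating the
#' map views. Both start with a biopsy; patient 1 proceeds directly to an
#' outpatient (specialist) visit after 55 days — the longest gap between any
#' two activities in the log — and is then sent to surgery, while patient 2
#' follows a longer route through mammography and a same-day ultrasound
#' before the visit and surgery. Mining this log yields a
#' Biopsy-to-Outpatient-visit edge traversed by one patient of the two
#' (case coverage 50%) with a median elapsed time of 55 days.
#'
#' @return an `event_log` tibble with two cases.
#' @export
#' @examples
#' m <- mine_map(example_log())
#' edge_statistic(m, "Biopsy", "Outpatient visit")
example_log <- function() {
  d0 <- as.Date("2018-01-08")
  as_event_log(tibble(
    case_id = c(rep("patient-1", 3L), rep("patient-2", 5L)),
    activity = c("Biopsy", "Outpatient visit", "BCT",
                 "Biopsy", "Mammography", "Ultrasound", "Outpatient visit",
                 "Mastectomy"),
    date = c(d0, d0 + 55, d0 + 75,
             d0 + 2, d0 + 14, d0 + 14, d0 + 32, d0 + 70),
    hospital_id = "HOSP-A",
    tariff_code = c("B-FNA", "V-FIRST", NA,
                    "B-ECR", "M-BIL", "U-BIL", "V-FIRST", NA),
    cost = c(0.71, 5.43, NA, 8.40, 4.10, 3.20, 5.43, NA)))
}
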