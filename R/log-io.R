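#' Write and read event logs as CSV
#'
#' Columns are `case_id`, `activity`, `date` (ISO 8601), `hospital_id`,
#' `tariff_code`, `cost`. Writing then reading is the identity.
#'
#' @param log an event log.
#' @param path file path.
#' @return `read_log_csv` returns an `event_log` tibble.
#' @export
write_log_csv <- function(log, path) {
  readr::write_csv(as_tibble(log), path, na = "")
  invisible(path)
}

#' @rdname write_log_csv
#' @export
read_log_csv <- function(path) {
  ev <- readr::read_csv(path, col_types = readr::cols(
    case_id = "c", activity = "c", date = "D", hospital_id = "c",
    tariff_code = "c", cost = "d"))
  probs <- readr::problems(ev)
  if (nrow(probs) > 0) {
    abort(sprintf("read_log_csv: malformed CSV at line(s) %s of %s",
                  paste(head(unique(probs$row), 10L), collapse = ", "), path))
  }
  as_event_log(ev)
}

#' Export an event log to XES
#'
#' Writes the standard XML interchange format for process-mining event
#' logs: one `<trace>` per case with the case id as `concept:name`, one
#' `<event>` per event with the activity as `concept:name` and the day as
#' `time:timestamp` at midnight UTC. The surgery hospital travels as
#' `org:resource`; tariff code and cost, when present, as literal
#' attributes.
#'
#' @param log an event log.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_xes <- function(log, path) {
  ev <- as_tibble(log)
  doc <- xml2::xml_new_root("log", "xes.version" = "1.0",
                            "xes.features" = "nested-attributes")
  xml2::xml_add_child(doc, "extension", name = "Concept", prefix = "concept",
                      uri = "http://www.xes-standard.org/concept.xesext")
  xml2::xml_add_child(doc, "extension", name = "Time", prefix = "time",
                      uri = "http://www.xes-standard.org/time.xesext")
  xml2::xml_add_child(doc, "classifier", name = "Activity",
                      keys = "concept:name")
  for (cid in unique(ev$case_id)) {
    tr <- xml2::xml_add_child(doc, "trace")
    xml2::xml_add_child(tr, "string", key = "concept:name", value = cid)
    sub <- ev[ev$case_id == cid, ]
    for (i in seq_len(nrow(sub))) {
      e <- xml2::xml_add_child(tr, "event")
      xml2::xml_add_child(e, "string", key = "concept:name",
                          value = sub$activity[i])
      xml2::xml_add_child(e, "date", key = "time:timestamp",
                          value = paste0(format(sub$date[i]), "T00:00:00.000+00:00"))
      xml2::xml_add_child(e, "string", key = "org:resource",
                          value = sub$hospital_id[i])
      if (!is.na(sub$tariff_code[i])) {
        xml2::xml_add_child(e, "string", key = "tariff_code",
                            value = sub$tariff_code[i])
        xml2::xml_add_child(e, "float", key = "cost",
                            value = format(sub$cost[i]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
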