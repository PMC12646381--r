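# Reading and writing the minimal OMOP CDM table subset used by the package:
# person, visit_occurrence, condition_occurrence, drug_exposure,
# procedure_occurrence, measurement. Comma-delimited, header row, ISO dates.

.omop_tables <- c("person", "visit_occurrence", "condition_occurrence",
                  "drug_exposure", "procedure_occurrence", "measurement")

.omop_domain_table <- c(diagnosis = "condition_occurrence",
                        medication = "drug_exposure",
                        procedure = "procedure_occurrence",
                        lab = "measurement")

.omop_code_col <- c(condition_occurrence = "condition_source_value",
                    drug_exposure = "drug_source_value",
                    procedure_occurrence = "procedure_source_value",
                    measurement = "measurement_source_value")

.omop_date_col <- c(condition_occurrence = "condition_start_date",
                    drug_exposure = "drug_exposure_start_date",
                    procedure_occurrence = "procedure_date",
                    measurement = "measurement_date")

#' Write a cohort as OMOP CDM delimited tables
#'
#' Emits the six-table minimal OMOP subset (person, visit_occurrence,
#' condition_occurrence, drug_exposure, procedure_occurrence, measurement) as
#' comma-delimited text files with header rows and ISO-8601 dates. Empty
#' domains still produce a header-only table. Lab values are printed with
#' full double precision so that [read_omop_tables()] reproduces the records
#' exactly.
#'
#' @param records an `ehr_cohort` or plain list of `ehr_record` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_omop_tables <- function(records, dir) {
  if (!length(records)) stop("records must be non-empty", call. = FALSE)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  }

  person <- data.frame(
    person_id = vapply(records, function(r) as.integer(r$person_id), integer(1)),
    gender_source_value = vapply(records, function(r) r$sex, character(1)),
    birth_datetime = vapply(records, function(r) format(r$birth_date), character(1)),
    stringsAsFactors = FALSE
  )

  visit_rows <- list(); event_rows <- list(); vid <- 0L; k <- 0L
  for (r in records) {
    for (v in r$visits) {
      vid <- vid + 1L; k <- k + 1L
      visit_rows[[k]] <- data.frame(
        visit_occurrence_id = vid, person_id = r$person_id,
        visit_start_date = format(v$date),
        visit_source_value = v$visit_type,
        discharge_to_source_value = if (is.na(v$discharge)) "" else v$discharge,
        stringsAsFactors = FALSE)
      if (nrow(v$events)) {
        ev <- v$events
        event_rows[[length(event_rows) + 1L]] <- data.frame(
          person_id = r$person_id, visit_occurrence_id = vid,
          event_date = format(v$date), domain = ev$domain, code = ev$code,
          value = ev$value, stringsAsFactors = FALSE)
      }
    }
  }
  visit_occurrence <- do.call(rbind, visit_rows)
  events <- if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame(person_id = numeric(0), visit_occurrence_id = integer(0),
               event_date = character(0), domain = character(0),
               code = character(0), value = numeric(0))

  paths <- character(0)
  write_one <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    paths <<- c(paths, path)
  }
  write_one(person, "person")
  write_one(visit_occurrence, "visit_occurrence")

  for (dom in names(.omop_domain_table)) {
    tab <- .omop_domain_table[[dom]]
    sub <- events[events$domain == dom, , drop = FALSE]
    n <- nrow(sub)
    df <- data.frame(id = seq_len(n), person_id = sub$person_id,
                     visit_occurrence_id = sub$visit_occurrence_id,
                     date = sub$event_date, code = sub$code,
                     stringsAsFactors = FALSE)
    names(df) <- c(paste0(tab, "_id"), "person_id", "visit_occurrence_id",
                   .omop_date_col[[tab]], .omop_code_col[[tab]])
    if (tab == "measurement") {
      # full precision so the write -> read round trip is exact
      df$value_as_number <- sprintf("%.17g", sub$value)
    }
    write_one(df, tab)
  }
  invisible(paths)
}

#' Read OMOP CDM delimited tables back into patient records
#'
#' Joins each domain table to its visit by `visit_occurrence_id`; events in a
#' visit carry the visit date. Orphan event rows (no matching visit) are
#' skipped with a warning; patients with zero visits are dropped with a
#' message reporting the count.
#'
#' @param dir directory containing the six tables written by
#'   [write_omop_tables()] (or any compatible OMOP extract).
#' @return an `ehr_cohort` list of `ehr_record` objects.
#' @export
read_omop_tables <- function(dir) {
  paths <- file.path(dir, paste0(.omop_tables, ".csv"))
  missing <- .omop_tables[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("%s table not found in '%s'", missing[1], dir), call. = FALSE)
  }
  tabs <- lapply(paths, function(p)
    utils::read.csv(p, stringsAsFactors = FALSE, colClasses = NA))
  names(tabs) <- .omop_tables

  person <- tabs$person
  visits <- tabs$visit_occurrence
  visit_person <- stats::setNames(visits$person_id, visits$visit_occurrence_id)
  visit_date <- stats::setNames(visits$visit_start_date, visits$visit_occurrence_id)

  all_events <- list(); n_orphan <- 0L
  for (dom in names(.omop_domain_table)) {
    tab <- .omop_domain_table[[dom]]
    df <- tabs[[tab]]
    if (!nrow(df)) next
    known <- as.character(df$visit_occurrence_id) %in% names(visit_person)
    n_orphan <- n_orphan + sum(!known)
    df <- df[known, , drop = FALSE]
    if (!nrow(df)) next
    all_events[[dom]] <- data.frame(
      visit_occurrence_id = df$visit_occurrence_id,
      domain = dom,
      code = as.character(df[[.omop_code_col[[tab]]]]),
      value = if (tab == "measurement") as.numeric(df$value_as_number) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (n_orphan > 0L) {
    warning(sprintf("skipped %d orphan event rows with no matching visit", n_orphan),
            call. = FALSE)
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else NULL
  events_by_visit <- if (!is.null(events)) split(events, events$visit_occurrence_id) else list()

  records <- list(); dropped <- 0L
  for (i in seq_len(nrow(person))) {
    pid <- person$person_id[i]
    pv <- visits[visits$person_id == pid, , drop = FALSE]
    if (!nrow(pv)) { dropped <- dropped + 1L; next }
    pv <- pv[order(as.Date(pv$visit_start_date), pv$visit_occurrence_id), , drop = FALSE]
    visit_list <- lapply(seq_len(nrow(pv)), function(j) {
      vid <- as.character(pv$visit_occurrence_id[j])
      ev <- events_by_visit[[vid]]
      if (is.null(ev)) {
        ev_df <- data.frame(domain = character(0), code = character(0),
                            value = numeric(0), stringsAsFactors = FALSE)
      } else {
        ord <- order(match(ev$domain, c("diagnosis", "procedure", "medication", "lab")),
                     ev$code)
        ev_df <- data.frame(domain = ev$domain[ord], code = ev$code[ord],
                            value = ev$value[ord], stringsAsFactors = FALSE)
      }
      dsc <- pv$discharge_to_source_value[j]
      list(date = as.Date(pv$visit_start_date[j]),
           visit_type = pv$visit_source_value[j],
           discharge = if (is.na(dsc) || !nzchar(dsc)) NA_character_ else dsc,
           events = ev_df)
    })
    records[[length(records) + 1L]] <- structure(
      list(person_id = pid, sex = person$gender_source_value[i],
           birth_date = as.Date(person$birth_datetime[i]), visits = visit_list),
      class = "ehr_record")
  }
  if (dropped > 0L) {
    message(sprintf("dropped %d patients with zero visits", dropped))
  }
  structure(records, class = "ehr_cohort")
}

#' Write rule ground truth as JSON
#'
#' @param ground_truth an `ehr_ground_truth` object from [simulate_ehr_cohort()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(ground_truth, path) {
  out <- list(
    events = ground_truth$events,
    rule_summary = ground_truth$rule_summary
  )
  jsonlite::write_json(out, path, dataframe = "columns", na = "null",
                       auto_unbox = TRUE, digits = NA, Date = "ISO8601")
  invisible(path)
}
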