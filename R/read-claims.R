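#' Read a dispensing claims table
#'
#' Reads a CSV of dispensing events, one row per dispensing, with a subject
#' identifier column and an ISO-8601 (`YYYY-MM-DD`) dispensing date column.
#' Column names are configurable. Dates are parsed strictly: any value that is
#' not a valid calendar date fails with an error naming the offending rows.
#'
#' @param path Path to the CSV file.
#' @param subject_col,date_col Column names in the file.
#' @return A tibble with columns `subject_id` (character) and
#'   `dispensing_date` (`Date`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,dispensing_date", "s1,2010-06-01", "s1,2010-06-28"), f)
#' read_dispensings(f)
#' @export
read_dispensings <- function(path, subject_col = "subject_id",
                             date_col = "dispensing_date") {
  tbl <- read_claims_csv(path, c(subject_col, date_col))
  tibble::tibble(
    subject_id = tbl[[subject_col]],
    dispensing_date = parse_iso_dates(tbl[[date_col]], path, date_col)
  )
}

#' Read an index-event table
#'
#' Reads a CSV with one index event (e.g. hospitalisation date) per subject.
#' Duplicate subject identifiers are an error, since the case-crossover design
#' admits exactly one event per subject.
#'
#' @inheritParams read_dispensings
#' @return A tibble with columns `subject_id` (character) and `event_date` (`Date`).
#' @export
read_events <- function(path, subject_col = "subject_id",
                        date_col = "event_date") {
  tbl <- read_claims_csv(path, c(subject_col, date_col))
  out <- tibble::tibble(
    subject_id = tbl[[subject_col]],
    event_date = parse_iso_dates(tbl[[date_col]], path, date_col)
  )
  dups <- unique(out$subject_id[duplicated(out$subject_id)])
  if (length(dups) > 0) {
    abort(sprintf(
      "Each subject must have exactly one event; duplicated subject id(s): %s",
      paste(dups, collapse = ", ")))
  }
  out
}

read_claims_csv <- function(path, required_cols) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(required_cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  blank <- which(is.na(tbl[[required_cols[1]]]) | tbl[[required_cols[1]]] == "")
  if (length(blank) > 0) {
    abort(sprintf("%s: empty subject id in data row(s): %s",
                  path, paste(blank, collapse = ", ")))
  }
  tbl
}

# Strict ISO-8601 civil-date parsing; impossible calendar dates (2010-13-40,
# 2010-02-30, ...) come back NA from as.Date and are reported by data row.
parse_iso_dates <- function(x, path, col) {
  parsed <- as.Date(x, format = "%Y-%m-%d")
  roundtrip_ok <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == x
  bad <- which(!roundtrip_ok)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: column `%s` has unparseable ISO-8601 date(s) in data row(s) %s (e.g. \"%s\")",
      path, col, paste(head(bad, 5), collapse = ", "), x[bad[1]]))
  }
  parsed
}

#' Build per-subject dispensing histories in days pre-event
#'
#' Joins dispensings to each subject's index event and converts calendar
#' dates to integer day offsets before the event (day 1 = the day immediately
#' before the event). Offsets outside `[1, horizon_days]` are dropped, as are
#' dispensings on or after the event date (they cannot precede the outcome);
#' multiple dispensings on one day collapse to a single offset, since exposure
#' is binary per day. Subjects with an event but no retained dispensings are
#' kept with an empty history. Dispensings for subjects absent from `events`
#' are skipped with a warning.
#'
#' @param dispensings Tibble from [read_dispensings()] (or equivalent).
#' @param events Tibble from [read_events()].
#' @param design A [cc_design()]; supplies `horizon_days`.
#' @return A tibble with one row per subject: `subject_id`, `event_date`, and
#'   `days_pre`, a list-column of strictly increasing integer offsets. The
#'   attribute `"drop_summary"` records per-subject input/kept/dropped row
#'   counts.
#' @export
build_histories <- function(dispensings, events, design) {
  stopifnot(inherits(design, "cc_design"))
  orphans <- setdiff(unique(dispensings$subject_id), events$subject_id)
  if (length(orphans) > 0) {
    warn(sprintf(
      "Skipping %d subject(s) with dispensings but no event: %s",
      length(orphans), paste(head(orphans, 5), collapse = ", ")))
    dispensings <- dplyr::filter(dispensings, !.data$subject_id %in% orphans)
  }

  offsets <- dispensings |>
    dplyr::inner_join(events, by = "subject_id") |>
    dplyr::mutate(days_pre = as.integer(.data$event_date - .data$dispensing_date),
                  kept = .data$days_pre >= 1L & .data$days_pre <= design$horizon_days)

  drop_summary <- offsets |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_in = dplyr::n(),
                     n_kept = sum(.data$kept),
                     n_dropped = sum(!.data$kept),
                     .groups = "drop")
  n_dropped <- sum(drop_summary$n_dropped)
  if (n_dropped > 0) {
    inform(sprintf(
      "Dropped %d dispensing(s) outside days 1-%d pre-event.",
      n_dropped, design$horizon_days))
  }

  histories <- offsets |>
    dplyr::filter(.data$kept) |>
    dplyr::distinct(.data$subject_id, .data$days_pre) |>
    dplyr::arrange(.data$subject_id, .data$days_pre) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(days_pre = list(.data$days_pre), .groups = "drop")

  out <- events |>
    dplyr::arrange(.data$subject_id) |>
    dplyr::left_join(histories, by = "subject_id") |>
    dplyr::mutate(days_pre = purrr::map(.data$days_pre, \(x) x %||% integer(0))) |>
    dplyr::select("subject_id", "event_date", "days_pre")
  attr(out, "drop_summary") <- drop_summary
  out
}
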