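#' Order a stratum's members for the timeline figure
#'
#' Members of strata A, B and C (unexposed in the case window) are sorted to
#' show the latest dispensing closest to the case window: ascending by the
#' latest-dispensing offset, so the subject whose last dispensing sits nearest
#' the case window is plotted first (top row). Members of D, E and F
#' (unexposed in the control windows) are sorted to show the earliest
#' dispensing closest to the control side: descending by the
#' earliest-dispensing offset. Ties break lexicographically by `subject_id`
#' so the layout is deterministic.
#'
#' @param stratum One of `"A"`--`"F"`.
#' @param members Tibble of member histories (`subject_id`, `days_pre`).
#' @return `members` reordered.
#' @export
sort_stratum <- function(stratum, members) {
  stratum <- match.arg(as.character(stratum), cc_strata[1:6])
  if (nrow(members) == 0) return(members)
  key <- purrr::map_int(members$days_pre, function(off) {
    if (length(off) == 0) return(NA_integer_)
    if (stratum %in% base::c("A", "B", "C")) min(off) else max(off)
  })
  ord <- if (stratum %in% base::c("A", "B", "C")) {
    order(key, members$subject_id)
  } else {
    order(-key, members$subject_id)
  }
  members[ord, , drop = FALSE]
}

#' Assemble the stratified timeline layout
#'
#' Builds the full figure layout: one panel per stratum A--F, members sorted
#' by the stratum's convention, annotated with the panel size, the rule
#' verdicts (when decisions are supplied) and the panel's share of the
#' strata A--F denominator. The orientation is fixed with the event at the
#' right of the timeline, so a window's right-hand side is the boundary
#' nearest the event.
#'
#' @param histories Tibble from [build_histories()].
#' @param classifications Tibble from [classify_cohort()]; recomputed from
#'   `histories` when omitted. Every classified subject must have a history.
#' @param design A [cc_design()].
#' @param decisions Optional `cc_rules` from [evaluate_rules()] supplying the
#'   panel verdict annotations.
#' @param panel_order Order of stratum panels, a permutation of `A`--`F`.
#' @return An object of class `cc_layout`: a list with `rows` (tibble
#'   `stratum`, `row`, `subject_id`, `days_pre` list-column), `panels`
#'   (per-stratum size, verdicts, percentage), `design`, and `orientation`.
#' @export
build_panels <- function(histories, design, classifications = NULL,
                         decisions = NULL, panel_order = LETTERS[1:6]) {
  stopifnot(inherits(design, "cc_design"))
  if (!setequal(panel_order, LETTERS[1:6])) {
    abort("`panel_order` must be a permutation of A-F.")
  }
  classifications <- classifications %||% classify_cohort(histories, design)
  strat <- assign_strata(classifications)
  missing_hist <- setdiff(strat$subject_id, histories$subject_id)
  if (length(missing_hist) > 0) {
    abort(sprintf("Classified subject(s) missing a history: %s",
                  paste(head(missing_hist, 5), collapse = ", ")))
  }

  denominator <- sum(strat$stratum %in% LETTERS[1:6])
  rows <- purrr::map(panel_order, function(s) {
    ids <- strat$subject_id[strat$stratum == s]
    members <- sort_stratum(s, dplyr::filter(histories, .data$subject_id %in% ids))
    if (nrow(members) == 0) {
      return(tibble::tibble(stratum = character(), row = integer(),
                            subject_id = character(), days_pre = list()))
    }
    tibble::tibble(stratum = s, row = seq_len(nrow(members)),
                   subject_id = members$subject_id,
                   days_pre = purrr::map(members$days_pre, sort))
  }) |> purrr::list_rbind()

  verdicts <- if (is.null(decisions)) {
    tibble::tibble(stratum = LETTERS[1:6],
                   verdict_cw1 = NA_character_, verdict_cw2 = NA_character_)
  } else {
    dplyr::select(tidy(decisions), "stratum", "verdict_cw1", "verdict_cw2")
  }
  panels <- tibble::tibble(stratum = panel_order) |>
    dplyr::left_join(dplyr::count(strat, .data$stratum, name = "n"),
                     by = "stratum") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct_of_denominator =
                    if (denominator > 0) 100 * .data$n / denominator else NA_real_) |>
    dplyr::left_join(verdicts, by = "stratum")

  structure(list(rows = rows, panels = panels, design = design,
                 orientation = "event_right"),
            class = "cc_layout")
}

#' @export
print.cc_layout <- function(x, ...) {
  cat(sprintf("<cc_layout: %d subjects across strata %s (event at right)>\n",
              nrow(x$rows), paste(x$panels$stratum, collapse = "")))
  print(x$panels)
  invisible(x)
}

#' Write a layout to a plain-text table
#'
#' Serialises the plotted rows as a TSV with columns `stratum`, `row`,
#' `subject_id`, `offsets` (semicolon-joined ascending day offsets), the
#' machine-readable counterpart of the figure used for regression testing
#' without image comparison.
#'
#' @param layout A `cc_layout` from [build_panels()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_layout <- function(layout, path) {
  stopifnot(inherits(layout, "cc_layout"))
  out <- layout$rows |>
    dplyr::mutate(offsets = purrr::map_chr(
      .data$days_pre, \(x) paste(sort(x), collapse = ";"))) |>
    dplyr::select("stratum", "row", "subject_id", "offsets")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a layout table written by [export_layout()]
#'
#' @param path Path to the TSV.
#' @return A tibble with `stratum`, `row`, `subject_id` and a `days_pre`
#'   integer list-column, matching the `rows` element of the exported layout.
#' @export
read_layout <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    stratum = readr::col_character(), row = readr::col_integer(),
    subject_id = readr::col_character(), offsets = readr::col_character()),
    progress = FALSE) |>
    dplyr::mutate(days_pre = purrr::map(
      .data$offsets, \(s) if (is.na(s) || s == "") integer(0)
                          else as.integer(strsplit(s, ";")[[1]]))) |>
    dplyr::select("stratum", "row", "subject_id", "days_pre")
}
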