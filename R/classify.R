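#' Is a subject exposed within a window?
#'
#' A subject is exposed in a window if at least one dispensing offset falls
#' inside the closed interval `[start, end]` in days pre-event.
#'
#' @param days_pre Integer vector of dispensing offsets for one subject.
#' @param window A [cc_window()].
#' @return A single logical.
#' @examples
#' exposed_in(c(30L, 120L), cc_window(1, 50))
#' @export
exposed_in <- function(days_pre, window) {
  stopifnot(inherits(window, "cc_window"))
  any(window_contains(window, days_pre))
}

#' Four-way exposure status for one subject under one control window
#'
#' From the two exposure booleans (case window, control window) a subject is
#' an *intermittent* user (case only), a *recent stopper* (control only), a
#' *continuous* user (both) or a *non-user* (neither). Dispensings falling
#' only in washout days count as exposure in neither window.
#'
#' @param days_pre Integer vector of dispensing offsets for one subject.
#' @param case_window,control_window [cc_window()]s.
#' @return One of `"intermittent"`, `"recent_stopper"`, `"continuous"`,
#'   `"non_user"` as a length-1 factor with those levels.
#' @examples
#' classify_exposure(c(30L, 120L), cc_window(1, 50), cc_window(101, 150))
#' @export
classify_exposure <- function(days_pre, case_window, control_window) {
  in_case <- exposed_in(days_pre, case_window)
  in_ctrl <- exposed_in(days_pre, control_window)
  status <- if (in_case && in_ctrl) "continuous"
  else if (in_case) "intermittent"
  else if (in_ctrl) "recent_stopper"
  else "non_user"
  as_status(status)
}

#' Classify a cohort's exposure status under both control windows
#'
#' Applies [classify_exposure()] to every subject, once per control window.
#' Because exposure in the case window is a single fact per subject, the two
#' statuses are always jointly admissible: a subject exposed in the case
#' window is `intermittent` or `continuous` under *both* windows, and one who
#' is not is `recent_stopper` or `non_user` under both.
#'
#' @param histories Tibble from [build_histories()].
#' @param design A [cc_design()].
#' @return A tibble with columns `subject_id`, `status_cw1`, `status_cw2`
#'   (factors with the four status levels).
#' @export
classify_cohort <- function(histories, design) {
  stopifnot(inherits(design, "cc_design"))
  histories |>
    dplyr::mutate(
      status_cw1 = purrr::map_vec(.data$days_pre, classify_exposure,
                                  design$case_window, design$control_window_1,
                                  .ptype = as_status(character())),
      status_cw2 = purrr::map_vec(.data$days_pre, classify_exposure,
                                  design$case_window, design$control_window_2,
                                  .ptype = as_status(character()))) |>
    dplyr::select("subject_id", "status_cw1", "status_cw2")
}

#' Data-driven window length from the repeat-dispensing distribution
#'
#' Suggests a common length for case/washout/control windows as the time
#' within which a given percentage of patients have a repeat dispensing. For
#' each subject with at least two dispensings a refill gap is extracted
#' (by default the gap between the first and second dispensing in calendar
#' order); the suggestion is the smallest observed gap `d` such that at least
#' `percentile`% of those gaps are `<= d` — an empirical quantile with no
#' interpolation, so the answer is always a whole number of observed days.
#'
#' @param histories Tibble from [build_histories()].
#' @param percentile Coverage percentage in `(0, 100]`; default 75.
#' @param gap_policy How to extract gaps per subject: `"first"` (first-to-
#'   second dispensing, the default), `"all"` (every successive gap, pooled),
#'   or `"median"` (per-subject median of successive gaps, rounded up).
#' @return A single integer number of days.
#' @examples
#' # four subjects with first-refill gaps 10, 20, 30, 40 days
#' h <- tibble::tibble(
#'   subject_id = as.character(1:4),
#'   event_date = as.Date("2010-07-01"),
#'   days_pre = list(c(10L, 20L), c(20L, 40L), c(50L, 80L), c(100L, 140L)))
#' suggest_window_length(h, percentile = 75)
#' @export
suggest_window_length <- function(histories, percentile = 75,
                                  gap_policy = c("first", "all", "median")) {
  gap_policy <- match.arg(gap_policy)
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile > 100) {
    abort("`percentile` must be a single number in (0, 100].")
  }
  # calendar order runs from the largest offset (earliest dispensing) down,
  # but successive gaps are the same either way
  subject_gaps <- purrr::map(histories$days_pre, function(off) {
    if (length(off) < 2) return(integer(0))
    diff(sort(off))
  })
  gaps <- switch(gap_policy,
    first = purrr::map_int(subject_gaps, \(g) if (length(g)) rev(g)[1] else NA_integer_),
    all = purrr::list_c(purrr::map(subject_gaps, as.integer)),
    median = purrr::map_int(subject_gaps,
                            \(g) if (length(g)) as.integer(ceiling(median(g))) else NA_integer_)
  )
  gaps <- gaps[!is.na(gaps)]
  if (length(gaps) == 0) {
    abort("No subject has a repeat dispensing; cannot suggest a window length.")
  }
  gaps <- sort(gaps)
  coverage <- seq_along(gaps) / length(gaps)
  as.integer(gaps[match(TRUE, coverage >= percentile / 100)])
}
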