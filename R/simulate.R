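#' Specify a block of synthetic subjects sharing an exposure archetype
#'
#' The generator plants dispensing patterns by archetype:
#' * `continuous_refiller` — refills across the whole horizon at gaps drawn
#'   from a positive-truncated normal, so the subject is exposed in the case
#'   window and both control windows. With a `course_window`, the subject is
#'   a *recent starter* instead: the earliest dispensing is planted inside
#'   that window and refills run forward in time to the event, which is the
#'   mechanism behind persistent-user bias when the start falls inside
#'   control window one.
#' * `intermittent_case_user` — a short course (1--2 dispensings) inside the
#'   case window only.
#' * `recent_stopper` — a short course inside a designated control window
#'   (control window one by default), nothing later.
#' * `non_user` — no dispensings.
#' * `washout_only_user` — a short course confined to the washout between the
#'   case window and control window one; exposure in neither window.
#'
#' @param archetype One of the five archetype names above.
#' @param count Number of subjects; non-negative.
#' @param refill_gap_mean,refill_gap_sd Refill-gap distribution in days
#'   (refillers only); the mean must be positive.
#' @param course_window Optional [cc_window()] overriding where the short
#'   course is planted (intermittent / stopper / washout archetypes).
#' @param n_course Range (length-2) of dispensings per short course.
#' @param jitter_days Uniform integer jitter applied to planted course
#'   offsets, clamped to the horizon.
#' @return An object of class `cc_archetype_spec`.
#' @export
archetype_spec <- function(archetype = base::c("continuous_refiller",
                                               "intermittent_case_user",
                                               "recent_stopper", "non_user",
                                               "washout_only_user"),
                           count,
                           refill_gap_mean = 30, refill_gap_sd = 0,
                           course_window = NULL, n_course = base::c(1L, 2L),
                           jitter_days = 0) {
  archetype <- match.arg(archetype)
  if (length(count) != 1 || is.na(count) || count < 0 || count != round(count)) {
    abort("`count` must be a single non-negative integer.")
  }
  if (refill_gap_mean <= 0) abort("`refill_gap_mean` must be positive.")
  if (!is.null(course_window)) course_window <- coerce_window(course_window, "course_window")
  structure(list(archetype = archetype, count = as.integer(count),
                 refill_gap_mean = refill_gap_mean,
                 refill_gap_sd = refill_gap_sd,
                 course_window = course_window,
                 n_course = as.integer(n_course),
                 jitter_days = as.integer(jitter_days)),
            class = "cc_archetype_spec")
}

#' Generate a synthetic claims cohort with known exposure structure
#'
#' Produces a dispensing table, an event table and a truth table from a list
#' of [archetype_spec()]s under a fixed seed. Event dates are distinct civil
#' dates drawn uniformly from a span wide enough for the cohort; dispensing
#' dates are derived from planted day offsets pre-event. The truth table's
#' statuses and strata are *recomputed from the emitted offsets*, not taken
#' from the archetype label, so stochastic jitter that genuinely moves a
#' subject's status is reflected in the truth.
#'
#' @param specs A single [archetype_spec()] or a list of them.
#' @param design A [cc_design()].
#' @param seed Integer seed; the same seed, specs and design reproduce the
#'   output byte for byte.
#' @param first_event_date Earliest possible event date.
#' @param id_prefix Prefix for generated subject ids.
#' @return A list with tibbles `dispensings` (`subject_id`,
#'   `dispensing_date`), `events` (`subject_id`, `event_date`) and `truth`
#'   (`subject_id`, `archetype`, `status_cw1`, `status_cw2`, `stratum`).
#' @examples
#' cohort <- generate_cohort(
#'   list(archetype_spec("continuous_refiller", 5),
#'        archetype_spec("intermittent_case_user", 3)),
#'   cc_design(), seed = 1)
#' cohort$truth
#' @export
generate_cohort <- function(specs, design, seed,
                            first_event_date = as.Date("2009-01-01"),
                            id_prefix = "S") {
  stopifnot(inherits(design, "cc_design"))
  if (inherits(specs, "cc_archetype_spec")) specs <- list(specs)
  if (!all(purrr::map_lgl(specs, inherits, "cc_archetype_spec"))) {
    abort("`specs` must be archetype_spec() objects.")
  }
  purrr::walk(specs, validate_spec_for_design, design = design)

  n_total <- sum(purrr::map_int(specs, "count"))
  local_seed(seed)
  # distinct civil event dates over a span of at least 4 years
  span <- max(1461L, n_total)
  event_dates <- first_event_date + sample.int(span, n_total) - 1L

  width <- max(3L, nchar(as.character(n_total)))
  ids <- sprintf(paste0(id_prefix, "%0", width, "d"), seq_len(n_total))

  archetypes <- unlist(purrr::map(specs, \(s) rep(s$archetype, s$count)))
  offsets <- purrr::list_flatten(
    purrr::map(specs, \(s) purrr::map(seq_len(s$count),
                                      \(i) plant_offsets(s, design))))

  truth <- tibble::tibble(
    subject_id = ids,
    archetype = archetypes,
    status_cw1 = purrr::map_vec(offsets, classify_exposure,
                                design$case_window, design$control_window_1,
                                .ptype = as_status(character())),
    status_cw2 = purrr::map_vec(offsets, classify_exposure,
                                design$case_window, design$control_window_2,
                                .ptype = as_status(character()))) |>
    dplyr::mutate(stratum = assign_stratum(.data$status_cw1, .data$status_cw2))

  events <- tibble::tibble(subject_id = ids, event_date = event_dates)
  dispensings <- tibble::tibble(subject_id = ids, event_date = event_dates,
                                days_pre = offsets) |>
    tidyr::unnest("days_pre") |>
    dplyr::mutate(dispensing_date = .data$event_date - .data$days_pre) |>
    dplyr::select("subject_id", "dispensing_date")

  list(dispensings = dispensings, events = events, truth = truth)
}

validate_spec_for_design <- function(spec, design) {
  win <- spec$course_window %||% default_course_window(spec$archetype, design)
  if (spec$archetype == "non_user" ||
      (spec$archetype == "continuous_refiller" && is.null(spec$course_window))) {
    return(invisible())
  }
  if (is.null(win)) {
    abort(sprintf("No feasible course window for archetype %s under this design.",
                  spec$archetype))
  }
  if (win$end > design$horizon_days) {
    abort(sprintf("Course window %s extends past the %d-day horizon.",
                  format(win), design$horizon_days))
  }
  invisible()
}

default_course_window <- function(archetype, design) {
  switch(archetype,
    intermittent_case_user = design$case_window,
    recent_stopper = design$control_window_1,
    washout_only_user = design_washout(design, "cw1"),
    NULL)
}

# emitted day offsets pre-event for one subject
plant_offsets <- function(spec, design) {
  horizon <- design$horizon_days
  off <- switch(spec$archetype,
    non_user = integer(0),
    continuous_refiller = {
      gaps_needed <- ceiling(horizon / max(1, spec$refill_gap_mean)) + 10
      gaps <- pmax(1, round(rnorm(gaps_needed, spec$refill_gap_mean,
                                  spec$refill_gap_sd)))
      if (is.null(spec$course_window)) {
        # long-term user: refills span the whole horizon
        first <- sample.int(max(1, min(gaps[1], horizon)), 1)
        off <- cumsum(base::c(first, gaps[-1]))
        while (max(off) <= horizon) { # top up if the gap draw ran short
          off <- base::c(off, max(off) + pmax(1, round(rnorm(
            5, spec$refill_gap_mean, spec$refill_gap_sd))))
        }
        off[off <= horizon]
      } else {
        # recent starter: earliest dispensing planted in course_window, then
        # refills run forward in time (decreasing offsets) to the event
        start <- sample(seq(spec$course_window$start, spec$course_window$end), 1)
        off <- start - cumsum(base::c(0, gaps))
        off[off >= 1]
      }
    },
    { # short-course archetypes
      win <- spec$course_window %||% default_course_window(spec$archetype, design)
      n <- if (spec$n_course[1] == spec$n_course[2]) spec$n_course[1]
           else sample(seq(spec$n_course[1], spec$n_course[2]), 1)
      n <- min(n, window_width(win))
      off <- sort(sample(seq(win$start, win$end), n))
      if (spec$jitter_days > 0) {
        off <- off + sample(seq(-spec$jitter_days, spec$jitter_days),
                            length(off), replace = TRUE)
        off <- pmin(pmax(off, 1L), horizon)
      }
      off
    })
  sort(unique(as.integer(off)))
}

# set.seed locally, restoring the caller's RNG state on exit
local_seed <- function(seed, env = parent.frame()) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  withr::defer({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
}

#' Compare planted truth with computed classifications
#'
#' Cross-tabulates the truth table's statuses against the classification
#' pipeline's output per control window. For deterministic archetypes the
#' agreement must be exact; the truth table is recomputed from emitted
#' offsets, so any disagreement indicates a defect in the date arithmetic or
#' classification, not generator noise.
#'
#' @param truth Truth tibble from [generate_cohort()].
#' @param classifications Tibble from [classify_cohort()] on the same cohort.
#' @return An object of class `cc_truth_report`: per-window confusion
#'   matrices (planted x computed) and agreement proportions.
#' @export
verify_truth <- function(truth, classifications) {
  joined <- dplyr::inner_join(truth, classifications, by = "subject_id",
                              suffix = base::c("_planted", "_computed"))
  if (nrow(joined) != nrow(truth)) {
    warn(sprintf("%d truth subject(s) missing from classifications.",
                 nrow(truth) - nrow(joined)))
  }
  confusion <- function(planted, computed) {
    table(planted = as_status(planted), computed = as_status(computed))
  }
  structure(
    list(n = nrow(joined),
         confusion_cw1 = confusion(joined$status_cw1_planted, joined$status_cw1_computed),
         confusion_cw2 = confusion(joined$status_cw2_planted, joined$status_cw2_computed),
         agreement_cw1 = mean(joined$status_cw1_planted == joined$status_cw1_computed),
         agreement_cw2 = mean(joined$status_cw2_planted == joined$status_cw2_computed)),
    class = "cc_truth_report")
}

#' @export
print.cc_truth_report <- function(x, ...) {
  cat(sprintf("<cc_truth_report: %d subjects>\n", x$n))
  cat(sprintf("  agreement: CW1 %.1f%%, CW2 %.1f%%\n",
              100 * x$agreement_cw1, 100 * x$agreement_cw2))
  invisible(x)
}
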