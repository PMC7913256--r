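#' Define an exposure window in days pre-event
#'
#' A window is a closed interval of integer day offsets before each subject's
#' index event. Day 1 is the day immediately before the event, so the window
#' "1--50 days pre fracture" is `cc_window(1, 50)`. On a timeline drawn with
#' the event at the right, `start` is the window's right-hand boundary
#' (nearest the event) and `end` its left-hand boundary.
#'
#' @param start First day of the window, in days pre-event (inclusive, >= 1).
#' @param end Last day of the window, in days pre-event (inclusive, > start).
#'
#' @return An object of class `cc_window` with elements `start` and `end`.
#' @examples
#' cc_window(101, 150)
#' @export
cc_window <- function(start, end) {
  start <- as_count(start, "start")
  end <- as_count(end, "end")
  if (start >= end) {
    abort("`start` must be strictly less than `end` (days pre-event).")
  }
  structure(list(start = start, end = end), class = "cc_window")
}

#' @export
print.cc_window <- function(x, ...) {
  cat(sprintf("<cc_window: %d-%d days pre-event (width %d)>\n",
              x$start, x$end, window_width(x)))
  invisible(x)
}

#' @export
format.cc_window <- function(x, ...) sprintf("%d-%d", x$start, x$end)

window_width <- function(window) window$end - window$start + 1L

window_contains <- function(window, offsets) {
  offsets >= window$start & offsets <= window$end
}

as_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x != round(x) || x < 1) {
    abort(sprintf("`%s` must be a single positive integer, got %s.",
                  name, deparse(x)))
  }
  as.integer(x)
}

#' Specify a case-crossover study design with two alternative control windows
#'
#' The design fixes the case window (immediately pre-event), two alternative
#' control windows further back in time, and the observation horizon. Washout
#' periods are not specified directly: the washout paired with each control
#' window is the derived gap between the end of the case window and the start
#' of that control window. Defaults follow the tricyclic-antidepressant /
#' hip-fracture worked example: case 1--50, control window one 101--150,
#' control window two 151--200, horizon 200 days.
#'
#' @param case_window,control_window_1,control_window_2 `cc_window` objects
#'   (or lists with `start`/`end`). Windows must be pairwise disjoint and
#'   ordered case < CW1 < CW2 moving away from the event.
#' @param horizon_days Observation span pre-event; must cover `control_window_2`.
#'
#' @return An object of class `cc_design`.
#' @examples
#' cc_design()
#' cc_design(case_window = cc_window(1, 30),
#'           control_window_1 = cc_window(61, 90),
#'           control_window_2 = cc_window(91, 120),
#'           horizon_days = 120)
#' @seealso [load_design()] to read a design from a YAML/JSON config file.
#' @export
cc_design <- function(case_window = cc_window(1, 50),
                      control_window_1 = cc_window(101, 150),
                      control_window_2 = cc_window(151, 200),
                      horizon_days = 200) {
  case_window <- coerce_window(case_window, "case_window")
  control_window_1 <- coerce_window(control_window_1, "control_window_1")
  control_window_2 <- coerce_window(control_window_2, "control_window_2")
  horizon_days <- as_count(horizon_days, "horizon_days")

  if (case_window$end >= control_window_1$start) {
    abort(sprintf(
      "Case window (%s) must end before control window one (%s) starts.",
      format(case_window), format(control_window_1)))
  }
  if (control_window_1$end >= control_window_2$start) {
    abort(sprintf(
      "Control window one (%s) must end before control window two (%s) starts.",
      format(control_window_1), format(control_window_2)))
  }
  if (horizon_days < control_window_2$end) {
    abort(sprintf(
      "`horizon_days` (%d) must reach at least the end of control window two (%d).",
      horizon_days, control_window_2$end))
  }
  design <- structure(
    list(case_window = case_window,
         control_window_1 = control_window_1,
         control_window_2 = control_window_2,
         horizon_days = horizon_days),
    class = "cc_design")

  if (is.null(design_washout(design, "cw1"))) {
    warn("Zero-width washout: control window one starts immediately after the case window.")
  }
  design
}

coerce_window <- function(x, name) {
  if (inherits(x, "cc_window")) return(x)
  if (is.list(x) && all(c("start", "end") %in% names(x))) {
    return(cc_window(x$start, x$end))
  }
  abort(sprintf("`%s` must be a cc_window or a list with `start` and `end`.", name))
}

#' Derived washout period for a control window
#'
#' The washout paired with a control window is the gap between the end of the
#' case window and the start of that control window (e.g. days 51--100 for a
#' case window 1--50 and control window 101--150).
#'
#' @param design A [cc_design()].
#' @param which `"cw1"` or `"cw2"`.
#' @return A `cc_window`, or `NULL` if the gap has zero width.
#' @export
design_washout <- function(design, which = c("cw1", "cw2")) {
  which <- match.arg(which)
  ctrl <- if (which == "cw1") design$control_window_1 else design$control_window_2
  lo <- design$case_window$end + 1L
  hi <- ctrl$start - 1L
  if (lo > hi) NULL else cc_window(lo, hi)
}

control_window <- function(design, which = c("cw1", "cw2")) {
  which <- match.arg(which)
  if (which == "cw1") design$control_window_1 else design$control_window_2
}

#' @export
print.cc_design <- function(x, ...) {
  cat("<cc_design>\n")
  cat(sprintf("  case window:      %s days pre-event\n", format(x$case_window)))
  w1 <- design_washout(x, "cw1")
  cat(sprintf("  washout (CW1):    %s\n", if (is.null(w1)) "none" else format(w1)))
  cat(sprintf("  control window 1: %s\n", format(x$control_window_1)))
  cat(sprintf("  control window 2: %s\n", format(x$control_window_2)))
  cat(sprintf("  horizon:          %d days\n", x$horizon_days))
  invisible(x)
}

#' Load a study design from a config file or list
#'
#' Reads a YAML or JSON mapping with entries `case_window`,
#' `control_window_1`, `control_window_2` (each `{start, end}` in days
#' pre-event) and `horizon_days`. Entries that are absent fall back to the
#' defaults of [cc_design()].
#'
#' @param config Path to a YAML/JSON file, or a named list with the same shape.
#' @return A validated [cc_design()].
#' @export
load_design <- function(config) {
  if (is.character(config)) {
    if (length(config) != 1) abort("`config` must be a single file path or a list.")
    if (!file.exists(config)) abort(sprintf("Design config not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a file path or a named list.")
  defaults <- list(case_window = cc_window(1, 50),
                   control_window_1 = cc_window(101, 150),
                   control_window_2 = cc_window(151, 200),
                   horizon_days = 200)
  args <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])
  cc_design(case_window = args$case_window,
            control_window_1 = args$control_window_1,
            control_window_2 = args$control_window_2,
            horizon_days = args$horizon_days)
}
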