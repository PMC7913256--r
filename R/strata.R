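#' Cross-window stratum from a pair of exposure statuses
#'
#' Subjects are stratified by how their exposure status changes when control
#' window two replaces control window one: A recent stopper -> non-user,
#' B non-user -> recent stopper, C recent stopper -> recent stopper,
#' D intermittent -> continuous, E continuous -> intermittent,
#' F intermittent -> intermittent. The two concordant strata G (continuous ->
#' continuous) and H (non-user -> non-user) feature no change and are not
#' assessed by the rule engine. Status pairs that contradict the case-window
#' exposure fact (e.g. intermittent -> non-user) are inadmissible.
#'
#' @param status_cw1,status_cw2 Vectors of exposure statuses (character or
#'   factor with levels `intermittent`, `recent_stopper`, `continuous`,
#'   `non_user`).
#' @return A factor with levels `A`--`H`, same length as the inputs.
#' @examples
#' assign_stratum("recent_stopper", "non_user")  # A
#' assign_stratum("continuous", "intermittent")  # E
#' @export
assign_stratum <- function(status_cw1, status_cw2) {
  key <- paste(as.character(status_cw1), as.character(status_cw2), sep = "->")
  map <- c("recent_stopper->non_user" = "A",
           "non_user->recent_stopper" = "B",
           "recent_stopper->recent_stopper" = "C",
           "intermittent->continuous" = "D",
           "continuous->intermittent" = "E",
           "intermittent->intermittent" = "F",
           "continuous->continuous" = "G",
           "non_user->non_user" = "H")
  stratum <- unname(map[key])
  if (anyNA(stratum)) {
    bad <- unique(key[is.na(stratum)])
    abort(sprintf(
      "Inadmissible status pair(s) (case-window exposure contradiction): %s",
      paste(bad, collapse = ", ")))
  }
  factor(stratum, levels = cc_strata)
}

#' Add the cross-window stratum to a classification table
#'
#' @param classifications Tibble from [classify_cohort()].
#' @return The input with a `stratum` factor column appended.
#' @export
assign_strata <- function(classifications) {
  dplyr::mutate(classifications,
                stratum = assign_stratum(.data$status_cw1, .data$status_cw2))
}

#' Distance from a dispensing to a window boundary
#'
#' On a timeline drawn with the event at the right, the right-hand side (RHS)
#' of a window is the boundary nearer the event — its `start` in days
#' pre-event — and the left-hand side (LHS) is its `end`.
#'
#' @param offset Integer day offset(s) pre-event.
#' @param window A [cc_window()].
#' @param side `"rhs"` (boundary nearer the event) or `"lhs"`.
#' @return Non-negative integer distance(s) in days.
#' @examples
#' boundary_distance(105, cc_window(101, 150), "rhs")  # 4
#' boundary_distance(105, cc_window(101, 150), "lhs")  # 45
#' @export
boundary_distance <- function(offset, window, side = c("rhs", "lhs")) {
  side <- match.arg(tolower(side), c("rhs", "lhs"))
  stopifnot(inherits(window, "cc_window"))
  if (any(offset != round(offset))) {
    abort("`offset` must be whole days pre-event.")
  }
  boundary <- if (side == "rhs") window$start else window$end
  as.integer(abs(as.integer(offset) - boundary))
}

# Reference dispensing per member: the latest dispensing (smallest offset)
# for strata whose members are unexposed in the case window (A, B, C), the
# earliest (largest offset) for those unexposed in the control window(s)
# (D, E, F).
reference_offset <- function(days_pre, stratum) {
  if (length(days_pre) == 0) return(NA_integer_)
  if (stratum %in% c("A", "B", "C")) min(days_pre) else max(days_pre)
}

# The per-member condition of each stratum's rule. Returns a tibble with the
# audit metric and the boolean. Ties ("closer to" with equal distances) count
# as NOT closer.
rule_condition <- function(stratum, days_pre, design) {
  cw1 <- design$control_window_1
  cw2 <- design$control_window_2
  ref <- reference_offset(days_pre, stratum)
  switch(stratum,
    A = { # latest dispensing closer to RHS of CW1 than LHS of CW1
      near <- boundary_distance(ref, cw1, "rhs")
      far <- boundary_distance(ref, cw1, "lhs")
      list(metric = far - near, meets = near < far)
    },
    B = { # any dispensing in the CW1 washout period
      washout <- design_washout(design, "cw1")
      n_wash <- if (is.null(washout) || length(days_pre) == 0) 0L
                else sum(window_contains(washout, days_pre))
      list(metric = n_wash, meets = n_wash > 0)
    },
    C = { # latest dispensing closer to RHS of CW1 than LHS of CW2
      near <- boundary_distance(ref, cw1, "rhs")
      far <- boundary_distance(ref, cw2, "lhs")
      list(metric = far - near, meets = near < far)
    },
    D = { # earliest dispensing closer to RHS of CW2 than LHS of CW2
      near <- boundary_distance(ref, cw2, "rhs")
      far <- boundary_distance(ref, cw2, "lhs")
      list(metric = far - near, meets = near < far)
    },
    E = { # earliest dispensing closer to LHS of CW1 than RHS of CW1
      near <- boundary_distance(ref, cw1, "lhs")
      far <- boundary_distance(ref, cw1, "rhs")
      list(metric = far - near, meets = near < far)
    },
    F = { # earliest dispensing inside the case window, not the washout
      in_case <- !is.na(ref) && window_contains(design$case_window, ref)
      list(metric = ref, meets = in_case)
    },
    abort(sprintf("No classification rule for stratum %s.", stratum))
  )
}

# verdict pairs (cw1, cw2) for the met / not-met branches of each rule
rule_verdicts <- list(
  A = list(met = c("correct", "misclassified"), unmet = c("misclassified", "correct")),
  B = list(met = c("misclassified", "correct"), unmet = c("correct", "misclassified")),
  C = list(met = c("correct", "correct"), unmet = c("misclassified", "misclassified")),
  D = list(met = c("misclassified", "correct"), unmet = c("correct", "misclassified")),
  E = list(met = c("correct", "misclassified"), unmet = c("misclassified", "correct")),
  F = list(met = c("correct", "correct"), unmet = c("misclassified", "misclassified"))
)

#' Apply one stratum's classification rule to its members
#'
#' Evaluates the deterministic correct-/mis-classification rule for a stratum
#' (A--F). Each rule asks whether a strict majority of members satisfy a
#' geometric condition on a reference dispensing — the latest dispensing for
#' strata A, B and C (whose members are unexposed in the case window), the
#' earliest for D, E and F (unexposed in the control windows) — relative to
#' the window boundaries, or, for stratum B, whether the member has any
#' washout dispensing. The verdict is issued for the stratum as a whole, one
#' verdict per control window; individual distances are returned so the
#' majority can be audited. "Closer to" ties are counted as not closer, and an
#' exactly-half split fails the strict majority.
#'
#' @param stratum One of `"A"`--`"F"`.
#' @param members Tibble of the stratum's members in the shape of
#'   [build_histories()] output (`subject_id`, `days_pre` list-column).
#'   Membership is checked: each member's recomputed status pair must map to
#'   `stratum`.
#' @param design A [cc_design()].
#' @return An object of class `cc_rule_decision`: a list with `stratum`,
#'   `n_members`, `n_meeting_condition`, `condition_met`, `verdict_cw1`,
#'   `verdict_cw2`, and `per_subject` (tibble of subject, metric, meets).
#'   An empty stratum yields `indeterminate` verdicts.
#' @export
evaluate_rule <- function(stratum, members, design) {
  stratum <- match.arg(as.character(stratum), cc_strata[1:6])
  stopifnot(inherits(design, "cc_design"))

  if (nrow(members) == 0) {
    return(new_rule_decision(stratum, members = tibble::tibble(
      subject_id = character(), metric = integer(), meets = logical()),
      condition_met = NA, verdict = c("indeterminate", "indeterminate")))
  }

  observed <- classify_cohort(members, design)
  observed_stratum <- assign_stratum(observed$status_cw1, observed$status_cw2)
  if (any(observed_stratum != stratum)) {
    bad <- members$subject_id[observed_stratum != stratum]
    abort(sprintf("Member(s) not in stratum %s: %s",
                  stratum, paste(head(bad, 5), collapse = ", ")))
  }

  per_subject <- purrr::map2(members$subject_id, members$days_pre, function(id, off) {
    cond <- rule_condition(stratum, off, design)
    tibble::tibble(subject_id = id, metric = as.integer(cond$metric),
                   meets = isTRUE(cond$meets))
  }) |> purrr::list_rbind()

  met <- sum(per_subject$meets) > nrow(per_subject) / 2
  verdict <- if (met) rule_verdicts[[stratum]]$met else rule_verdicts[[stratum]]$unmet
  if (!met && stratum %in% c("C", "F")) {
    warn(sprintf(
      "Stratum %s majority failed its condition: classified as misclassified under both control windows.",
      stratum))
  }
  new_rule_decision(stratum, per_subject, met, verdict)
}

new_rule_decision <- function(stratum, members, condition_met, verdict) {
  structure(
    list(stratum = stratum,
         n_members = nrow(members),
         n_meeting_condition = sum(members$meets),
         condition_met = condition_met,
         verdict_cw1 = verdict[1],
         verdict_cw2 = verdict[2],
         per_subject = members),
    class = "cc_rule_decision")
}

#' @export
print.cc_rule_decision <- function(x, ...) {
  cat(sprintf("<cc_rule_decision: stratum %s>\n", x$stratum))
  cat(sprintf("  members: %d, meeting condition: %d (majority %s)\n",
              x$n_members, x$n_meeting_condition,
              if (isTRUE(x$condition_met)) "met" else if (isFALSE(x$condition_met)) "not met" else "n/a"))
  cat(sprintf("  verdicts: CW1 %s, CW2 %s\n", x$verdict_cw1, x$verdict_cw2))
  invisible(x)
}

#' @export
tidy.cc_rule_decision <- function(x, ...) {
  tibble::tibble(stratum = x$stratum, n = x$n_members,
                 n_meeting_condition = x$n_meeting_condition,
                 condition_met = x$condition_met,
                 verdict_cw1 = x$verdict_cw1, verdict_cw2 = x$verdict_cw2)
}

#' Run the full rule engine over strata A--F
#'
#' Stratifies the cohort, evaluates each stratum's rule, and collects the
#' decisions.
#'
#' @param histories Tibble from [build_histories()].
#' @param classifications Tibble from [classify_cohort()]; recomputed from
#'   `histories` when omitted.
#' @param design A [cc_design()].
#' @return An object of class `cc_rules`: a list of `cc_rule_decision`s named
#'   `A`--`F`, with the stratified classification table attached. [tidy()]
#'   returns one row per stratum; [summarize_misclassification()] turns it
#'   into cohort-level percentages.
#' @export
evaluate_rules <- function(histories, design, classifications = NULL) {
  stopifnot(inherits(design, "cc_design"))
  classifications <- classifications %||% classify_cohort(histories, design)
  strat <- assign_strata(classifications)
  missing_hist <- setdiff(strat$subject_id, histories$subject_id)
  if (length(missing_hist) > 0) {
    abort(sprintf("Classified subject(s) missing a history: %s",
                  paste(head(missing_hist, 5), collapse = ", ")))
  }
  decisions <- purrr::map(rlang::set_names(cc_strata[1:6]), function(s) {
    ids <- strat$subject_id[strat$stratum == s]
    evaluate_rule(s, dplyr::filter(histories, .data$subject_id %in% ids), design)
  })
  structure(decisions, classifications = strat, class = "cc_rules")
}

#' @export
tidy.cc_rules <- function(x, ...) {
  purrr::list_rbind(purrr::map(unclass(x), tidy))
}

#' @export
print.cc_rules <- function(x, ...) {
  cat("<cc_rules: Table-of-rules verdicts for strata A-F>\n")
  print(tidy(x))
  invisible(x)
}

#' Cohort-level correct-/mis-classification percentages
#'
#' Aggregates stratum verdicts into the percentage of subjects correctly
#' classified and potentially misclassified under each control window. The
#' denominator is the number of subjects in strata A--F (the strata featuring
#' a change in exposure status); each stratum contributes its whole size to
#' the verdict its rule issued for that window.
#'
#' @param rules A `cc_rules` object from [evaluate_rules()], or a list of
#'   `cc_rule_decision`s covering every non-empty stratum A--F.
#' @param denominator Override for the percentage denominator; defaults to the
#'   total membership of strata A--F.
#' @return An object of class `cc_misclass_summary`. [tidy()] gives the
#'   per-stratum breakdown, [glance()] the one-row percentage summary.
#' @export
summarize_misclassification <- function(rules, denominator = NULL) {
  decisions <- tidy_decisions(rules)
  denominator <- denominator %||% sum(decisions$n)
  if (denominator <= 0) {
    abort("No subjects in strata A-F: nothing to summarise.")
  }
  decisions <- dplyr::mutate(decisions, pct = 100 * .data$n / denominator)
  pct_for <- function(col, verdict) {
    sum(decisions$pct[decisions[[col]] == verdict & decisions$n > 0])
  }
  structure(
    list(strata = decisions,
         denominator = denominator,
         percent_correct_cw1 = pct_for("verdict_cw1", "correct"),
         percent_misclassified_cw1 = pct_for("verdict_cw1", "misclassified"),
         percent_indeterminate_cw1 = pct_for("verdict_cw1", "indeterminate"),
         percent_correct_cw2 = pct_for("verdict_cw2", "correct"),
         percent_misclassified_cw2 = pct_for("verdict_cw2", "misclassified"),
         percent_indeterminate_cw2 = pct_for("verdict_cw2", "indeterminate")),
    class = "cc_misclass_summary")
}

tidy_decisions <- function(rules) {
  if (inherits(rules, "cc_rules")) return(tidy(rules))
  if (is.list(rules) && all(purrr::map_lgl(rules, inherits, "cc_rule_decision"))) {
    return(purrr::list_rbind(purrr::map(rules, tidy)))
  }
  abort("`rules` must come from evaluate_rules() or be a list of rule decisions.")
}

#' @export
print.cc_misclass_summary <- function(x, ...) {
  cat(sprintf("<cc_misclass_summary: %d subjects in strata A-F>\n", x$denominator))
  cat(sprintf("  CW1: %.1f%% correct, %.1f%% misclassified\n",
              x$percent_correct_cw1, x$percent_misclassified_cw1))
  cat(sprintf("  CW2: %.1f%% correct, %.1f%% misclassified\n",
              x$percent_correct_cw2, x$percent_misclassified_cw2))
  invisible(x)
}

#' @export
tidy.cc_misclass_summary <- function(x, ...) x$strata

#' @export
glance.cc_misclass_summary <- function(x, ...) {
  tibble::tibble(
    denominator = x$denominator,
    percent_correct_cw1 = x$percent_correct_cw1,
    percent_misclassified_cw1 = x$percent_misclassified_cw1,
    percent_indeterminate_cw1 = x$percent_indeterminate_cw1,
    percent_correct_cw2 = x$percent_correct_cw2,
    percent_misclassified_cw2 = x$percent_misclassified_cw2,
    percent_indeterminate_cw2 = x$percent_indeterminate_cw2)
}
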