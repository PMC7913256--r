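test_that("the status-pair to stratum mapping is total over admissible pairs", {
  pairs <- list(
    c("recent_stopper", "non_user", "A"),
    c("non_user", "recent_stopper", "B"),
    c("recent_stopper", "recent_stopper", "C"),
    c("intermittent", "continuous", "D"),
    c("continuous", "intermittent", "E"),
    c("intermittent", "intermittent", "F"),
    c("continuous", "continuous", "G"),
    c("non_user", "non_user", "H"))
  for (p in pairs) {
    expect_equal(as.character(assign_stratum(p[1], p[2])), p[3])
  }
  # injective: the 8 admissible pairs give 8 distinct strata
  got <- vapply(pairs, \(p) as.character(assign_stratum(p[1], p[2])), "")
  expect_equal(sort(got), LETTERS[1:8])
  # case-window contradiction
  expect_error(assign_stratum("intermittent", "non_user"), "Inadmissible")
  expect_error(assign_stratum("non_user", "continuous"), "Inadmissible")
})

test_that("boundary distances treat the event-side boundary as the RHS", {
  cw1 <- cc_window(101, 150)
  expect_equal(boundary_distance(105, cw1, "rhs"), 4L)
  expect_equal(boundary_distance(105, cw1, "lhs"), 45L)
  expect_equal(boundary_distance(101, cw1, "rhs"), 0L)
  expect_error(boundary_distance(125.5, cw1, "rhs"), "whole days")
})

test_that("rule A: majority of latest dispensings near the case-side boundary
           of CW1 means correct with CW1, misclassified with CW2", {
  d <- default_design()
  # recent stoppers under CW1, non-users under CW2; distances to RHS(101) are
  # {2, 9, 47}, to LHS(150) {47, 40, 2}: two of three are closer to the RHS
  members <- make_histories(list(103L, 110L, 148L))
  dec <- evaluate_rule("A", members, d)
  expect_equal(dec$n_meeting_condition, 2L)
  expect_true(dec$condition_met)
  expect_equal(c(dec$verdict_cw1, dec$verdict_cw2), c("correct", "misclassified"))
  # mirrored branch
  dec2 <- evaluate_rule("A", make_histories(list(148L, 149L, 103L)), d)
  expect_false(dec2$condition_met)
  expect_equal(c(dec2$verdict_cw1, dec2$verdict_cw2), c("misclassified", "correct"))
})

test_that("rule B: washout dispensings flip the verdict towards CW2", {
  d <- default_design()
  # non-users under CW1 becoming recent stoppers under CW2 (dispensing in CW2),
  # two of three with an extra washout dispensing
  met <- make_histories(list(c(75L, 160L), c(90L, 190L), 170L))
  dec <- evaluate_rule("B", met, d)
  expect_true(dec$condition_met)
  expect_equal(c(dec$verdict_cw1, dec$verdict_cw2), c("misclassified", "correct"))
  # no washout dispensings: the complement branch (the one observed in
  # practice) keeps CW1 correct
  unmet <- evaluate_rule("B", make_histories(list(160L, 170L, 190L)), d)
  expect_equal(unmet$n_meeting_condition, 0L)
  expect_equal(c(unmet$verdict_cw1, unmet$verdict_cw2), c("correct", "misclassified"))
})

test_that("rules C and F issue a joint verdict, warning on the complement", {
  d <- default_design()
  # stoppers in both windows, latest dispensing near CW1's event-side boundary
  dec_c <- evaluate_rule("C", make_histories(list(c(105L, 160L), c(130L, 180L))), d)
  expect_true(dec_c$condition_met)
  expect_equal(c(dec_c$verdict_cw1, dec_c$verdict_cw2), c("correct", "correct"))

  # intermittent users whose earliest dispensing is in the case window
  dec_f <- evaluate_rule("F", make_histories(list(30L, c(10L, 45L))), d)
  expect_true(dec_f$condition_met)
  expect_equal(c(dec_f$verdict_cw1, dec_f$verdict_cw2), c("correct", "correct"))
  # earliest dispensing in the washout instead: misclassified in both, warned
  expect_warning(
    dec_f2 <- evaluate_rule("F", make_histories(list(c(30L, 60L), c(20L, 95L))), d),
    "misclassified under both")
  expect_equal(c(dec_f2$verdict_cw1, dec_f2$verdict_cw2),
               c("misclassified", "misclassified"))

  # rule C's complement needs a control window much wider than the gap to
  # CW2's far boundary; under such a design it warns the same way
  wide <- cc_design(case_window = cc_window(1, 10),
                    control_window_1 = cc_window(21, 120),
                    control_window_2 = cc_window(121, 140),
                    horizon_days = 140)
  expect_warning(
    dec_c2 <- evaluate_rule("C", make_histories(list(c(120L, 130L))), wide),
    "misclassified under both")
  expect_equal(c(dec_c2$verdict_cw1, dec_c2$verdict_cw2),
               c("misclassified", "misclassified"))
})

test_that("rules D and E compare the earliest dispensing with control-window
           boundaries", {
  d <- default_design()
  # intermittent -> continuous; earliest offsets 152 and 195: distances to
  # CW2's RHS(151) are {1, 44}, to its LHS(200) {48, 5}
  dec_d <- evaluate_rule("D", make_histories(list(c(30L, 152L), c(20L, 195L))), d)
  expect_equal(dec_d$n_meeting_condition, 1L)
  expect_false(dec_d$condition_met)  # exactly half is not a strict majority
  expect_equal(c(dec_d$verdict_cw1, dec_d$verdict_cw2), c("correct", "misclassified"))
  dec_d2 <- evaluate_rule("D", make_histories(list(c(30L, 152L))), d)
  expect_true(dec_d2$condition_met)
  expect_equal(c(dec_d2$verdict_cw1, dec_d2$verdict_cw2), c("misclassified", "correct"))

  # continuous -> intermittent; earliest 149 is 1 day from CW1's LHS(150) and
  # 48 from its RHS(101): the persistent-user pattern
  dec_e <- evaluate_rule("E", make_histories(list(c(30L, 149L), c(40L, 145L))), d)
  expect_true(dec_e$condition_met)
  expect_equal(c(dec_e$verdict_cw1, dec_e$verdict_cw2), c("correct", "misclassified"))
  dec_e2 <- evaluate_rule("E", make_histories(list(c(30L, 105L), c(40L, 102L), c(45L, 149L))), d)
  expect_false(dec_e2$condition_met)
  expect_equal(c(dec_e2$verdict_cw1, dec_e2$verdict_cw2), c("misclassified", "correct"))
})

test_that("equidistant dispensings are not 'closer' and half-splits fail the
           strict majority", {
  # CW1 101-149 has an integer midpoint at 125
  d <- cc_design(control_window_1 = cc_window(101, 149))
  dec <- evaluate_rule("A", make_histories(list(125L)), d)
  expect_equal(dec$n_meeting_condition, 0L)
  expect_false(dec$condition_met)
  expect_equal(dec$per_subject$metric, 0L)
})

test_that("membership and emptiness contracts hold", {
  d <- default_design()
  expect_error(evaluate_rule("A", make_histories(list(30L)), d), "not in stratum A")
  empty <- evaluate_rule("C", make_histories(list())[0, ], d)
  expect_equal(empty$n_members, 0L)
  expect_equal(c(empty$verdict_cw1, empty$verdict_cw2),
               c("indeterminate", "indeterminate"))
})

test_that("mirroring offsets inside CW1 flips rule A for odd member counts", {
  d <- default_design()
  cw1 <- d$control_window_1
  set.seed(23)
  for (i in 1:20) {
    offs <- sample(cw1$start:cw1$end, 5, replace = TRUE)
    dec <- evaluate_rule("A", make_histories(as.list(offs)), d)
    mirrored <- cw1$start + cw1$end - offs
    dec_m <- evaluate_rule("A", make_histories(as.list(mirrored)), d)
    # window width is even, so no member can be equidistant (no ties)
    expect_equal(dec_m$condition_met, !dec$condition_met)
  }
})

test_that("misclassification percentages aggregate stratum sizes over the
           A-F denominator", {
  d <- default_design()
  # ten members per stratum, each engineered to satisfy its rule's condition
  # except B (kept washout-free so its complement branch fires, matching the
  # verdict pattern observed in practice: CW1 correct for A, B, C, E, F)
  decisions <- list(
    evaluate_rule("A", rep_histories(103L, 10, "a"), d),
    evaluate_rule("B", rep_histories(160L, 10, "b"), d),
    evaluate_rule("C", rep_histories(c(110L, 160L), 10, "c"), d),
    evaluate_rule("D", rep_histories(c(30L, 152L), 10, "d"), d),
    evaluate_rule("E", rep_histories(c(30L, 149L), 10, "e"), d),
    evaluate_rule("F", rep_histories(30L, 10, "f"), d))
  s <- summarize_misclassification(decisions)
  expect_equal(s$denominator, 60L)
  expect_equal(s$percent_correct_cw1, 100 * 50 / 60)
  expect_equal(s$percent_misclassified_cw1, 100 * 10 / 60)
  expect_equal(s$percent_correct_cw2, 50)
  expect_equal(s$percent_misclassified_cw2, 50)
  expect_equal(s$percent_correct_cw1 + s$percent_misclassified_cw1 +
                 s$percent_indeterminate_cw1, 100)
  expect_equal(glance(s)$percent_correct_cw2, 50)

  # a single non-empty stratum with a joint 'correct' verdict
  only_c <- summarize_misclassification(
    list(evaluate_rule("C", rep_histories(c(110L, 160L), 3, "c"), d)))
  expect_equal(only_c$percent_correct_cw1, 100)
  expect_equal(only_c$percent_correct_cw2, 100)

  # nothing to summarise
  empty <- lapply(LETTERS[1:6], \(s) evaluate_rule(s, make_histories(list())[0, ], d))
  expect_error(summarize_misclassification(empty), "No subjects")
})

test_that("the full rule engine reproduces per-stratum decisions from raw
           histories", {
  d <- default_design()
  h <- dplyr::bind_rows(
    rep_histories(103L, 3, "a"),       # stratum A
    rep_histories(c(75L, 160L), 2, "b"), # stratum B, washout dispensing
    rep_histories(30L, 4, "f"))        # stratum F
  rules <- evaluate_rules(h, d)
  td <- tidy(rules)
  expect_equal(td$n[td$stratum %in% c("A", "B", "F")], c(3L, 2L, 4L))
  expect_equal(td$verdict_cw1[td$stratum == "B"], "misclassified")
  expect_equal(td$verdict_cw1[td$stratum == "C"], "indeterminate")
  expect_error(evaluate_rules(h[1:3, ], d,
                              classifications = classify_cohort(h, d)),
               "missing a history")
})
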