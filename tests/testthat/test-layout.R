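test_that("stratum sorting follows the published conventions with stable
           tie-breaks", {
  # A: ascending by latest dispensing (nearest the case window first)
  a <- make_histories(list(148L, 103L, 110L), ids = c("x", "y", "z"))
  expect_equal(sort_stratum("A", a)$subject_id, c("y", "z", "x"))
  # E: descending by earliest dispensing, ties lexicographic by id
  e <- make_histories(list(c(5L, 20L), c(7L, 45L), c(3L, 45L)),
                      ids = c("m20", "m45b", "m45a"))
  expect_equal(sort_stratum("E", e)$subject_id, c("m45a", "m45b", "m20"))
  # single member and empty input are fixed points
  single <- make_histories(list(30L))
  expect_equal(sort_stratum("F", single), single)
  expect_equal(nrow(sort_stratum("C", single[0, ])), 0)
  # sorting is a permutation
  expect_setequal(sort_stratum("A", a)$subject_id, a$subject_id)
})

one_per_stratum <- function() {
  make_histories(
    list(103L,            # A
         c(75L, 160L),    # B
         c(110L, 160L),   # C
         c(30L, 152L),    # D
         c(30L, 149L),    # E
         30L),            # F
    ids = paste0("s", LETTERS[1:6]))
}

test_that("panels hold every subject exactly once, sized and annotated", {
  d <- default_design()
  h <- one_per_stratum()
  rules <- evaluate_rules(h, d)
  lay <- build_panels(h, d, decisions = rules)
  expect_equal(nrow(lay$rows), 6)
  expect_equal(lay$panels$n, rep(1L, 6))
  expect_equal(lay$panels$pct_of_denominator, rep(100 / 6, 6))
  expect_equal(lay$panels$verdict_cw1[lay$panels$stratum == "A"], "correct")
  expect_false(any(duplicated(lay$rows$subject_id)))
  expect_equal(lay$orientation, "event_right")

  # an empty stratum keeps its panel with n = 0
  h5 <- h[h$subject_id != "sC", ]
  lay5 <- build_panels(h5, d)
  expect_equal(lay5$panels$n[lay5$panels$stratum == "C"], 0L)
  expect_equal(sum(lay5$panels$n), 5L)

  # concordant subjects (strata G, H) are not plotted
  h8 <- dplyr::bind_rows(h, make_histories(list(c(30L, 120L, 160L), integer(0)),
                                           ids = c("sG", "sH")))
  lay8 <- build_panels(h8, d)
  expect_equal(sum(lay8$panels$n), 6L)
  expect_false(any(c("sG", "sH") %in% lay8$rows$subject_id))

  expect_error(build_panels(h[1:3, ], d,
                            classifications = classify_cohort(h, d)),
               "missing a history")
  expect_error(build_panels(h, d, panel_order = c("A", "B")), "permutation")
})

test_that("row counts are conserved on a ten-per-stratum synthetic cohort", {
  d <- default_design()
  h <- dplyr::bind_rows(
    rep_histories(103L, 10, "a"), rep_histories(c(75L, 160L), 10, "b"),
    rep_histories(c(110L, 160L), 10, "c"), rep_histories(c(30L, 152L), 10, "d"),
    rep_histories(c(30L, 149L), 10, "e"), rep_histories(30L, 10, "f"))
  lay <- build_panels(h, d)
  expect_equal(lay$panels$n, rep(10L, 6))
  expect_equal(nrow(lay$rows), 60)
  expect_equal(as.vector(tapply(lay$rows$row, lay$rows$stratum, max)),
               rep(10L, 6))
})

test_that("the layout export round-trips and is byte-identical across runs", {
  d <- default_design()
  h <- one_per_stratum()
  lay <- build_panels(h, d)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_layout(lay, f1)
  export_layout(build_panels(h[sample(6), ], d), f2)  # shuffled input
  expect_identical(readLines(f1), readLines(f2))

  back <- read_layout(f1)
  expect_equal(back$subject_id, lay$rows$subject_id)
  expect_equal(back$days_pre, lay$rows$days_pre)
  expect_equal(back$row, lay$rows$row)

  # offsets serialize ascending regardless of insertion order
  lay2 <- lay
  lay2$rows$days_pre[[2]] <- rev(lay2$rows$days_pre[[2]])
  f3 <- withr::local_tempfile(fileext = ".tsv")
  export_layout(lay2, f3)
  expect_identical(readLines(f3), readLines(f1))
})

test_that("the timeline figure plots one marker per dispensing with window
           bands, and renders to svg and png", {
  d <- default_design()
  h <- one_per_stratum()
  lay <- build_panels(h, d, decisions = evaluate_rules(h, d))
  p <- autoplot(lay)
  built <- ggplot2::ggplot_build(p)
  marker_layer <- built$data[[2]]
  expect_equal(nrow(marker_layer), sum(lengths(lay$rows$days_pre)))
  band_layer <- built$data[[1]]
  expect_equal(nrow(band_layer) / length(unique(band_layer$PANEL)), 4)

  empty <- build_panels(h[0, ], d)
  expect_error(autoplot(empty), "Empty layout")

  svg_file <- withr::local_tempfile(fileext = ".svg")
  png_file <- withr::local_tempfile(fileext = ".png")
  render_timeline(lay, svg_file)
  render_timeline(lay, png_file, width = 5, height = 4)
  expect_gt(file.size(svg_file), 0)
  expect_gt(file.size(png_file), 0)
  # markers in the vector output sit at their day offsets
  expect_match(paste(readLines(svg_file), collapse = ""), "<svg")
  expect_error(render_timeline(lay, withr::local_tempfile(fileext = ".pdf")),
               "Unsupported format")
})
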