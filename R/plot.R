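#' Plot the stratified dispensing timeline
#'
#' Draws the misclassification-assessment figure: one panel per stratum A--F,
#' one horizontal row per subject, a tick per dispensing, and shaded bands
#' for the case window, washout period(s) and the two control windows. The
#' x axis counts days pre-event and is reversed so the event sits at the
#' right edge — a window's right-hand side is then literally the boundary
#' nearest the event. Panel headers show the stratum, its size, its share of
#' the strata A--F denominator and, when the layout carries rule decisions,
#' the verdict under each control window.
#'
#' @param object A `cc_layout` from [build_panels()].
#' @param band_alpha Transparency of the window bands.
#' @param band_colors Named colors for the `case`, `washout`, `cw1`, `cw2`
#'   bands.
#' @param marker_shape Plotting symbol per dispensing (default `"|"`).
#' @param marker_size Symbol size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cc_layout <- function(object,
                               band_alpha = 0.25,
                               band_colors = base::c(case = "#d95f02",
                                                     washout = "grey70",
                                                     cw1 = "#1b9e77",
                                                     cw2 = "#7570b3"),
                               marker_shape = "|", marker_size = 3, ...) {
  design <- object$design
  points <- tidyr::unnest(object$rows, "days_pre")
  if (nrow(points) == 0) abort("Empty layout: nothing to plot.")

  labels <- object$panels |>
    dplyr::mutate(label = sprintf(
      "%s  (n = %d, %s%%)%s", .data$stratum, .data$n,
      ifelse(is.na(.data$pct_of_denominator), "-",
             formatC(.data$pct_of_denominator, format = "f", digits = 1)),
      ifelse(is.na(.data$verdict_cw1), "",
             sprintf("  CW1: %s / CW2: %s", .data$verdict_cw1, .data$verdict_cw2))))
  points$stratum <- factor(points$stratum, levels = labels$stratum)

  bands <- window_bands(design)
  ggplot2::ggplot(points) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$band),
      ymin = -Inf, ymax = Inf, alpha = band_alpha, inherit.aes = FALSE) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$days_pre, y = .data$row),
      shape = marker_shape, size = marker_size) +
    ggplot2::scale_x_reverse(limits = base::c(design$horizon_days + 1, 0),
                             expand = ggplot2::expansion(0)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = band_colors, name = NULL) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$stratum), scales = "free_y", space = "free_y",
      labeller = ggplot2::as_labeller(
        rlang::set_names(labels$label, labels$stratum))) +
    ggplot2::labs(x = "Days pre-event (event at right)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank(),
                   strip.text.y = ggplot2::element_text(angle = 0, hjust = 0),
                   legend.position = "bottom")
}

# shaded day-ranges for the design's windows; band edges extend half a day so
# a closed day interval [a, b] covers its whole days on a continuous axis
window_bands <- function(design) {
  band_row <- function(win, band) {
    if (is.null(win)) return(NULL)
    tibble::tibble(band = band, xmin = win$end + 0.5, xmax = win$start - 0.5)
  }
  purrr::list_rbind(purrr::compact(list(
    band_row(design$case_window, "case"),
    band_row(design_washout(design, "cw1"), "washout"),
    band_row(design$control_window_1, "cw1"),
    band_row(design$control_window_2, "cw2"))))
}

#' @export
plot.cc_layout <- function(x, ...) print(autoplot(x, ...))

#' Render a layout to an image file
#'
#' @param layout A `cc_layout` from [build_panels()].
#' @param path Output file path.
#' @param format `"svg"` or `"png"`; defaults to the file extension.
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution (png only).
#' @param ... Passed to [autoplot.cc_layout()].
#' @return `path`, invisibly.
#' @export
render_timeline <- function(layout, path, format = NULL,
                            width = 9, height = 7, dpi = 150, ...) {
  stopifnot(inherits(layout, "cc_layout"))
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% base::c("svg", "png")) {
    abort(sprintf("Unsupported format \"%s\": use \"svg\" or \"png\".", format))
  }
  p <- autoplot(layout, ...)
  device <- switch(format,
    svg = grDevices::svg,
    png = function(filename, ...) grDevices::png(filename, ..., type = "cairo"))
  ggplot2::ggsave(path, plot = p, device = device, width = width,
                  height = height, dpi = dpi)
  invisible(path)
}
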