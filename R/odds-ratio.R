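#' Tally exposure statuses for a control window
#'
#' Counts the four exposure statuses under the chosen control window.
#' Continuous users and non-users are concordant between the case and control
#' windows and drop out of the self-matched analysis; intermittent users
#' (exposed in the case window only) and recent stoppers (control window only)
#' are the discordant subjects whose ratio estimates the odds ratio.
#'
#' @param classifications Tibble from [classify_cohort()].
#' @param window `"cw1"`, `"cw2"`, or both (the default) for one row each.
#' @return A tibble with columns `window`, `n_continuous`, `n_non_user`,
#'   `n_intermittent`, `n_recent_stopper`.
#' @export
discordant_counts <- function(classifications, window = c("cw1", "cw2")) {
  window <- match.arg(window, several.ok = TRUE)
  purrr::map(window, function(w) {
    status <- as_status(classifications[[paste0("status_", w)]])
    counts <- table(status)
    tibble::tibble(window = w,
                   n_continuous = as.integer(counts[["continuous"]]),
                   n_non_user = as.integer(counts[["non_user"]]),
                   n_intermittent = as.integer(counts[["intermittent"]]),
                   n_recent_stopper = as.integer(counts[["recent_stopper"]]))
  }) |> purrr::list_rbind()
}

#' Discordant-pair odds ratio with Wald confidence interval
#'
#' For a 1:1 self-matched design with binary exposure, the conditional
#' maximum-likelihood estimate of the odds ratio is the ratio of discordant
#' counts, `OR = b / c`, where `b` subjects are exposed in the case window
#' only and `c` in the control window only. The confidence interval is the
#' Wald interval on the log scale,
#' `exp(log(b/c) +/- z * sqrt(1/b + 1/c))` — the standard matched-pairs
#' (McNemar-type) interval, identical to the output of a univariable
#' conditional logistic regression with subjects as strata.
#'
#' @param b Number exposed in the case window only (intermittent users), or a
#'   one-row data frame from [discordant_counts()] supplying both counts.
#' @param c Number exposed in the control window only (recent stoppers).
#' @param alpha Two-sided significance level; default 0.05 for a 95% CI.
#' @param continuity_correction If `TRUE`, add 0.5 to both discordant cells
#'   (Haldane--Anscombe) so zero cells are estimable; otherwise a zero cell is
#'   an error.
#' @return An object of class `cc_or` with elements `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `alpha`, `b`, `c`, `method`. Use [tidy()] or [glance()] for
#'   a one-row tibble.
#' @examples
#' odds_ratio(127, 108)  # OR 1.18, 95% CI 0.91-1.52
#' @export
odds_ratio <- function(b, c, alpha = 0.05, continuity_correction = FALSE) {
  if (is.data.frame(b)) {
    counts <- b
    if (nrow(counts) != 1 ||
        !all(base::c("n_intermittent", "n_recent_stopper") %in% names(counts))) {
      abort("Data-frame input must be a single row with n_intermittent and n_recent_stopper.")
    }
    b <- counts$n_intermittent
    c <- counts$n_recent_stopper
  }
  stopifnot(length(b) == 1, length(c) == 1, b >= 0, c >= 0)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  if ((b == 0 || c == 0) && !continuity_correction) {
    abort(paste0(
      "Degenerate discordant table (b = ", b, ", c = ", c, "): the odds ratio ",
      "is undefined or infinite with an empty discordant cell. Enable ",
      "`continuity_correction` to add 0.5 to both cells."))
  }
  corrected <- continuity_correction && (b == 0 || c == 0)
  bb <- b + if (corrected) 0.5 else 0
  cc <- c + if (corrected) 0.5 else 0
  z <- qnorm(1 - alpha / 2)
  log_or <- log(bb / cc)
  se <- sqrt(1 / bb + 1 / cc)
  structure(
    list(odds_ratio = bb / cc,
         ci_lower = exp(log_or - z * se),
         ci_upper = exp(log_or + z * se),
         alpha = alpha,
         b = b, c = c,
         method = if (corrected) "wald_log_or_haldane" else "wald_log_or"),
    class = "cc_or")
}

#' @export
print.cc_or <- function(x, ...) {
  cat(sprintf("<cc_or: discordant-pair odds ratio (b = %s, c = %s)>\n", x$b, x$c))
  cat(sprintf("  OR %.2f, %d%% CI %.2f-%.2f\n", x$odds_ratio,
              round(100 * (1 - x$alpha)), x$ci_lower, x$ci_upper))
  invisible(x)
}

#' @export
tidy.cc_or <- function(x, ...) {
  tibble::tibble(estimate = x$odds_ratio, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, alpha = x$alpha,
                 n_case_only = x$b, n_control_only = x$c, method = x$method)
}

#' @export
glance.cc_or <- function(x, ...) tidy(x)

#' Case-crossover effect estimates for both control windows
#'
#' The one-call analysis: tallies exposure statuses and computes the
#' discordant-pair odds ratio and confidence interval per control window,
#' mirroring the exposure-classification-and-effect table of a two-window
#' sensitivity analysis.
#'
#' @param classifications Tibble from [classify_cohort()].
#' @inheritParams odds_ratio
#' @return A tibble with one row per control window: the four status counts
#'   plus `or`, `ci_lower`, `ci_upper`.
#' @export
estimate_effects <- function(classifications, alpha = 0.05,
                             continuity_correction = FALSE) {
  discordant_counts(classifications) |>
    dplyr::rowwise() |>
    dplyr::mutate({
      fit <- odds_ratio(.data$n_intermittent, .data$n_recent_stopper,
                        alpha = alpha,
                        continuity_correction = continuity_correction)
      tibble::tibble(or = fit$odds_ratio, ci_lower = fit$ci_lower,
                     ci_upper = fit$ci_upper)
    }) |>
    dplyr::ungroup()
}
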