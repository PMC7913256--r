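# shared fixtures built in code

`%||%` <- function(x, y) if (is.null(x)) y else x

default_design <- function() suppressWarnings(cc_design())

# histories tibble from a list of offset vectors (one element per subject)
make_histories <- function(offsets, ids = NULL,
                           event_date = as.Date("2010-07-01")) {
  ids <- ids %||% sprintf("s%03d", seq_along(offsets))
  tibble::tibble(subject_id = ids, event_date = event_date,
                 days_pre = lapply(offsets, as.integer))
}

# n copies of one offset vector, distinct ids with a prefix
rep_histories <- function(offsets, n, prefix) {
  make_histories(rep(list(offsets), n), ids = sprintf("%s%03d", prefix, seq_len(n)))
}

write_claims_files <- function(dispensings, events, dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  dfile <- file.path(dir, "dispensings.csv")
  efile <- file.path(dir, "events.csv")
  readr::write_csv(dispensings, dfile, progress = FALSE)
  readr::write_csv(events, efile, progress = FALSE)
  list(dispensings = dfile, events = efile, dir = dir)
}

# brute-force conditional-likelihood oracle for the 1:1 self-matched odds
# ratio: b + c Bernoulli trials with success probability or/(1 + or),
# maximised by golden-section search on the log-odds scale
conditional_mle_or <- function(b, c) {
  loglik <- function(log_or) {
    p <- exp(log_or) / (1 + exp(log_or))
    b * log(p) + c * log(1 - p)
  }
  exp(stats::optimize(loglik, interval = c(-15, 15),
                      maximum = TRUE, tol = 1e-12)$maximum)
}
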