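#' Complete-case filtering of a participant table
#'
#' Drops every row with a missing value in any of the required covariates.
#' No imputation is performed. The number of excluded rows is recorded in the
#' `n_excluded` attribute of the result (also readable with
#' [n_excluded()]).
#'
#' @param data Participant table (one row per participant).
#' @param required_covariates Character vector of column names that must be
#'   non-missing; defaults to every column.
#' @return The filtered tibble with attribute `n_excluded`.
#' @export
complete_case_filter <- function(data, required_covariates = names(data)) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(required_covariates, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("required covariate(s) not present: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[, required_covariates, drop = FALSE])
  if (!any(keep)) abort("complete-case filtering excluded every row.")
  out <- as_tibble(data[keep, , drop = FALSE])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' @rdname complete_case_filter
#' @export
n_excluded <- function(data) attr(data, "n_excluded") %||% 0L

#' Outcome-stratified 50/50 split
#'
#' Splits a participant table into a training/validation set and a test set,
#' sampling independently within the event and non-event strata so both
#' halves retain (up to rounding) the same outcome proportion. Within each
#' stratum the test count is `round(stratum size * test_fraction)` (R's
#' round-half-to-even).
#'
#' @param data Participant table with an `event` column coded 0/1.
#' @param test_fraction Fraction assigned to the test set, in (0,1).
#' @param seed Optional integer seed; the split is deterministic given it.
#' @return An object of class `split_result`: a list with tibbles `train`
#'   and `test`.
#' @export
stratified_split <- function(data, test_fraction = 0.5, seed = NULL) {
  stopifnot(is.data.frame(data), "event" %in% names(data))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("`test_fraction` must lie strictly in (0, 1).")
  }
  if (!all(data$event %in% c(0, 1))) abort("`event` must be coded 0/1.")
  n1 <- sum(data$event == 1)
  n0 <- sum(data$event == 0)
  if (n1 == 0 || n0 == 0) abort("both outcome classes must be present to stratify.")

  test_idx <- .with_seed(seed, {
    idx <- integer(0)
    for (cls in c(0, 1)) {
      rows <- which(data$event == cls)
      k <- round(length(rows) * test_fraction)
      idx <- c(idx, sample(rows, k))
    }
    sort(idx)
  })
  structure(
    list(
      train = as_tibble(data[-test_idx, , drop = FALSE]),
      test = as_tibble(data[test_idx, , drop = FALSE])
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result>\n")
  cat(sprintf("  train: %d rows (%d events)  test: %d rows (%d events)\n",
              nrow(x$train), sum(x$train$event),
              nrow(x$test), sum(x$test$event)))
  invisible(x)
}

#' Random oversampling of the minority (event) class
#'
#' Duplicates randomly chosen event rows, with replacement, until the event
#' count matches the non-event count. All original rows are retained;
#' duplicates keep their original `id` and are marked with an incrementing
#' `replicate` counter (originals carry 0) so bootstrap bookkeeping stays
#' auditable. A table that is already balanced — or in which the event class
#' is the majority — is returned unchanged. Intended for the
#' training/validation half only; the test half must stay untouched.
#'
#' @param data Participant table with an `event` column coded 0/1.
#' @param seed Optional integer seed.
#' @return The augmented tibble.
#' @export
oversample_minority <- function(data, seed = NULL) {
  stopifnot(is.data.frame(data), "event" %in% names(data))
  if (!all(data$event %in% c(0, 1))) abort("`event` must be coded 0/1.")
  n1 <- sum(data$event == 1)
  n0 <- sum(data$event == 0)
  if (n1 == 0) abort("no event rows to oversample.")
  if (n1 >= n0) return(as_tibble(data))

  event_rows <- which(data$event == 1)
  extra <- .with_seed(seed, sample(event_rows, n0 - n1, replace = TRUE))
  out <- dplyr::bind_rows(
    mutate(as_tibble(data), replicate = 0L),
    mutate(as_tibble(data[extra, , drop = FALSE]), replicate = 1L)
  )
  # number duplicates per source id: 1, 2, ... in sampling order
  dup <- out$replicate == 1L
  out$replicate[dup] <- stats::ave(rep(1L, sum(dup)), out$id[dup],
                                   FUN = seq_along)
  out
}

#' Binary outcome labels for classification models
#'
#' Returns the event indicator as an integer 0/1 vector. Participants
#' censored before the horizon are labelled 0: the classification models
#' deliberately ignore censoring and time-to-event, modelling only whether
#' the event was observed.
#'
#' @param data Participant table with an `event` column.
#' @return Integer vector of 0/1 labels.
#' @export
binary_outcome_label <- function(data) {
  stopifnot(is.data.frame(data), "event" %in% names(data))
  if (!all(data$event %in% c(0, 1))) abort("`event` must be coded 0/1.")
  as.integer(data$event)
}
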