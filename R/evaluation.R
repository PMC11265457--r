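#' Threshold classification metrics with confidence intervals
#'
#' Dichotomizes risk scores at a threshold (prediction = score >= threshold)
#' and reports accuracy, sensitivity, specificity, and positive predictive
#' value from the confusion counts, each with a confidence interval on its
#' own denominator: the normal approximation
#' \eqn{p \pm z\sqrt{p(1-p)/m}} by default, or the Wilson score interval.
#' PPV is undefined (reported `NA` with `ppv_defined = FALSE`) when no
#' positive predictions are made.
#'
#' @param labels 0/1 outcome labels.
#' @param scores Risk scores on the same scale as `threshold`.
#' @param threshold Classification threshold (default 0.5).
#' @param alpha Two-sided significance level.
#' @param ci `"normal"` (default) or `"wilson"`.
#' @return A one-row tibble of class `classification_metrics` with the
#'   confusion counts and each metric with its interval.
#' @export
threshold_metrics <- function(labels, scores, threshold = 0.5, alpha = 0.05,
                              ci = c("normal", "wilson")) {
  ci <- match.arg(ci)
  if (length(labels) != length(scores)) abort("`labels` and `scores` lengths differ.")
  if (!all(labels %in% c(0, 1))) abort("`labels` must be coded 0/1.")
  if (length(unique(labels)) < 2) abort("both outcome classes must be present.")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  n <- length(labels)
  z <- qnorm(1 - alpha / 2)

  interval <- function(k, m) {
    if (m == 0) return(c(NA_real_, NA_real_, NA_real_))
    p <- k / m
    if (ci == "normal") {
      half <- z * sqrt(p * (1 - p) / m)
      c(p, max(0, p - half), min(1, p + half))
    } else {
      center <- (p + z^2 / (2 * m)) / (1 + z^2 / m)
      half <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / (1 + z^2 / m)
      c(p, max(0, center - half), min(1, center + half))
    }
  }
  acc <- interval(tp + tn, n)
  sens <- interval(tp, tp + fn)
  spec <- interval(tn, tn + fp)
  ppv <- interval(tp, tp + fp)

  out <- tibble(
    n = n, threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = acc[1], accuracy_lo = acc[2], accuracy_hi = acc[3],
    sensitivity = sens[1], sensitivity_lo = sens[2], sensitivity_hi = sens[3],
    specificity = spec[1], specificity_lo = spec[2], specificity_hi = spec[3],
    ppv = ppv[1], ppv_lo = ppv[2], ppv_hi = ppv[3],
    ppv_defined = (tp + fp) > 0
  )
  structure(out, class = c("classification_metrics", class(out)))
}

# product-limit survival at a single time point, lean vector version
.km_surv_at <- function(time, event, t0) {
  keep <- event == 1 & time <= t0
  if (!any(keep)) return(1)
  et <- sort(unique(time[keep]))
  s <- 1
  for (tt in et) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

#' Time-dependent (cumulative/dynamic) AUC under censoring
#'
#' Discrimination of a baseline risk score for events occurring by a
#' horizon, estimated with the nearest-neighbour bivariate survival
#' estimator: the conditional survival \eqn{S(t \mid \mathrm{score})} is a
#' Kaplan-Meier estimate over the symmetric score-percentile neighbourhood
#' of each subject (half-width `span`), from which time-dependent
#' sensitivity and specificity are built and the ROC curve integrated by the
#' trapezoid rule. Because only score ranks enter, the estimate is invariant
#' under strictly monotone transforms of the scores; without censoring
#' before the horizon it approaches the Mann-Whitney concordance between
#' by-horizon cases and controls.
#'
#' @param time Follow-up times in years.
#' @param event 0/1 event indicators.
#' @param scores Baseline risk scores (higher = riskier).
#' @param horizon Horizon in years (default 5).
#' @param span Neighbourhood half-width on the score-percentile scale;
#'   default \eqn{0.25\,n^{-0.20}}.
#' @return The AUC at the horizon, a number in \[0, 1\].
#' @export
time_dependent_auc <- function(time, event, scores, horizon = 5, span = NULL) {
  n <- length(time)
  if (length(event) != n || length(scores) != n) abort("input lengths differ.")
  if (!all(is.finite(scores))) abort("scores must be finite.")
  if (!any(event == 1 & time <= horizon)) abort("no events before the horizon.")
  span <- span %||% (0.25 * n^(-0.20))

  pct <- rank(scores, ties.method = "average") / n
  ord <- order(pct)
  pct_s <- pct[ord]
  time_s <- time[ord]
  event_s <- event[ord]

  # sliding percentile window (two pointers over the score-sorted subjects)
  S_i <- numeric(n)
  lo <- 1L; hi <- 1L
  for (i in seq_len(n)) {
    while (pct_s[lo] < pct_s[i] - span) lo <- lo + 1L
    while (hi < n && pct_s[hi + 1L] <= pct_s[i] + span) hi <- hi + 1L
    w <- lo:hi
    S_i[i] <- .km_surv_at(time_s[w], event_s[w], horizon)
  }
  S_marg <- mean(S_i)

  # cutoffs at unique score percentiles (ascending)
  last_of <- which(pct_s != c(pct_s[-1], Inf))  # last index of each tie block
  cum_S <- cumsum(S_i)
  F_c <- last_of / n                         # P(score <= c)
  Scum <- (cum_S[n] - cum_S[last_of]) / n    # P(score > c, T > t)
  sens <- pmin(1, pmax(0, (1 - F_c - Scum) / (1 - S_marg)))
  fpr <- pmin(1, pmax(0, Scum / S_marg))

  sens <- c(1, sens, 0)
  fpr <- c(1, fpr, 0)
  sum((fpr[-length(fpr)] - fpr[-1]) * (sens[-length(sens)] + sens[-1]) / 2)
}

#' Per-subgroup calibration of predicted risks
#'
#' Compares, within each risk subgroup, the mean predicted risk against the
#' observed Kaplan-Meier event rate at the horizon. For a well-calibrated
#' model the two columns track each other across subgroups.
#'
#' @param data Participant table with `event`, `time`, a score column, and
#'   a `.risk_group` column.
#' @param horizon Horizon in years (default 5).
#' @param score Name of the predicted-risk column.
#' @return A tibble with one row per subgroup: `risk_group`, `n`,
#'   `mean_predicted`, `observed_rate`, `observed_se`.
#' @export
calibration_by_subgroup <- function(data, horizon = 5, score = ".risk") {
  .check_participants(data)
  if (!".risk_group" %in% names(data)) abort("no `.risk_group` column; partition first.")
  if (!score %in% names(data)) abort(paste0("score column `", score, "` not found."))
  sc <- data[[score]]
  if (any(sc < 0 | sc > 1)) abort("calibration needs probabilistic scores in [0, 1].")

  bind_rows(lapply(sort(unique(data$.risk_group)), function(g) {
    sub <- data[data$.risk_group == g, ]
    if (nrow(sub) == 0) abort("empty subgroup.")
    obs <- event_rate_at(km_estimate(sub$time, sub$event), horizon)
    tibble(risk_group = g, n = nrow(sub),
           mean_predicted = mean(sub[[score]]),
           observed_rate = obs$rate, observed_se = sqrt(obs$var))
  }))
}

#' Calibration plot: predicted vs observed event rate by subgroup
#'
#' @param calibration A [calibration_by_subgroup()] result (optionally with
#'   a `model` column to facet by).
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  p <- ggplot2::ggplot(calibration,
                       ggplot2::aes(x = .data$mean_predicted,
                                    y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$observed_rate - 1.96 * .data$observed_se,
      ymax = .data$observed_rate + 1.96 * .data$observed_se)) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed event rate (KM)")
  if ("model" %in% names(calibration)) {
    p <- p + ggplot2::facet_wrap(~model)
  }
  p
}
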