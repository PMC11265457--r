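#' Kaplan-Meier product-limit estimate with Greenwood variance
#'
#' Computes \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over the
#' distinct event times, with the Greenwood variance
#' \eqn{\hat S(t)^2 \sum_{t_i \le t} d_i / (n_i (n_i - d_i))}. Censored
#' observations leave the risk set without contributing a factor. Where the
#' estimate reaches 0 the variance is reported as 0 (the Greenwood sum is
#' undefined there).
#'
#' @param time Follow-up times in years, all > 0.
#' @param event 0/1 event indicators (1 = event at `time`, 0 = censored).
#' @return An object of class `km_curve`: a tibble with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `surv`, `var`), with
#'   attributes `n` (subjects) and `max_time` (last observed time, event or
#'   censoring). \eqn{\hat S(0) = 1} is implicit.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) abort("empty input.")
  if (length(time) != length(event)) abort("`time` and `event` lengths differ.")
  if (!all(is.finite(time)) || any(time <= 0)) abort("times must be finite and > 0.")
  if (!all(event %in% c(0, 1))) abort("`event` must be coded 0/1.")

  ord <- order(time)
  t_s <- time[ord]
  d_s <- event[ord]
  ut <- unique(t_s)
  idx <- match(t_s, ut)
  d_t <- as.vector(rowsum(d_s, idx, reorder = TRUE))
  m_t <- tabulate(idx, nbins = length(ut))
  n_risk <- length(time) - c(0, cumsum(m_t))[seq_along(ut)]

  frac <- 1 - d_t / n_risk
  surv <- cumprod(frac)
  gw <- ifelse(n_risk > d_t, d_t / (n_risk * (n_risk - d_t)), 0)
  var <- surv^2 * cumsum(gw)
  var[surv == 0] <- 0

  keep <- d_t > 0
  out <- tibble(
    time = ut[keep],
    n_risk = as.integer(n_risk[keep]),
    n_event = as.integer(d_t[keep]),
    surv = surv[keep],
    var = var[keep]
  )
  structure(out, class = c("km_curve", class(out)),
            n = length(time), max_time = max(time))
}

#' Event rate at a horizon from a Kaplan-Meier curve
#'
#' Returns \eqn{1 - \hat S(t)} using the last event time at or before `t`,
#' together with the Greenwood variance of \eqn{\hat S(t)}. If `t` lies
#' beyond the last observed follow-up time the rate at the last time is
#' returned with `extrapolated = TRUE` and a warning.
#'
#' @param curve A [km_estimate()] result.
#' @param t Horizon in years (>= 0).
#' @return A list with `rate`, `var`, and `extrapolated`.
#' @export
event_rate_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  extrapolated <- t > attr(curve, "max_time")
  if (extrapolated) {
    warn(sprintf("horizon %.3g y exceeds last observed time %.3g y; using the last estimate.",
                 t, attr(curve, "max_time")))
    t <- attr(curve, "max_time")
  }
  i <- findInterval(t, curve$time)
  if (i == 0) return(list(rate = 0, var = 0, extrapolated = extrapolated))
  list(rate = 1 - curve$surv[i], var = curve$var[i], extrapolated = extrapolated)
}

#' Absolute risk reduction between two Kaplan-Meier curves
#'
#' The ARR at horizon `t` is the control-arm event rate minus the
#' treated-arm event rate, each from its Kaplan-Meier curve. The standard
#' error is the square root of the summed Greenwood variances and the
#' confidence interval is the symmetric normal approximation
#' \eqn{\mathrm{ARR} \pm z_{1-\alpha/2}\,\mathrm{SE}}.
#'
#' @param control_curve,treated_curve [km_estimate()] results per arm.
#' @param t Horizon in years.
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return A one-row tibble of class `arr_estimate` with columns
#'   `rate_control`, `rate_treated`, `arr`, `se`, `arr_lo`, `arr_hi`,
#'   `n_control`, `n_treated`, `horizon`, `alpha`.
#' @export
arr_with_ci <- function(control_curve, treated_curve, t, alpha = 0.05) {
  stopifnot(inherits(control_curve, "km_curve"),
            inherits(treated_curve, "km_curve"))
  if (attr(control_curve, "n") == 0 || attr(treated_curve, "n") == 0) {
    abort("degenerate arm: no subjects at risk.")
  }
  rc <- event_rate_at(control_curve, t)
  rt <- event_rate_at(treated_curve, t)
  arr <- rc$rate - rt$rate
  se <- sqrt(rc$var + rt$var)
  z <- qnorm(1 - alpha / 2)
  out <- tibble(
    rate_control = rc$rate, rate_treated = rt$rate,
    arr = arr, se = se, arr_lo = arr - z * se, arr_hi = arr + z * se,
    n_control = attr(control_curve, "n"), n_treated = attr(treated_curve, "n"),
    horizon = t, alpha = alpha
  )
  structure(out, class = c("arr_estimate", class(out)))
}

#' Per-subgroup absolute risk reduction table
#'
#' For every risk subgroup, fits a Kaplan-Meier curve per arm and computes
#' the ARR at the horizon with its Greenwood-based confidence interval. This
#' is the machine-readable subgroup-results table of the analysis.
#'
#' Subgroups with fewer than `min_per_arm` participants in either arm make
#' the Kaplan-Meier contrast unstable; by default they raise an error, or
#' with `small_groups = "merge"` they are merged into the adjacent
#' lower-risk subgroup (group indices are then renumbered consecutively).
#'
#' @param data Participant table with `arm`, `event`, `time`, and a
#'   `.risk_group` column.
#' @param horizon Horizon in years (default 5).
#' @param alpha Two-sided significance level.
#' @param min_per_arm Minimum participants per arm per subgroup (default 10).
#' @param small_groups `"error"` (default) or `"merge"`.
#' @return A tibble with one row per subgroup: `risk_group`, `n_control`,
#'   `n_treated`, `rate_control`, `rate_treated`, `arr`, `se`, `arr_lo`,
#'   `arr_hi`.
#' @export
arr_by_subgroup <- function(data, horizon = 5, alpha = 0.05,
                            min_per_arm = 10,
                            small_groups = c("error", "merge")) {
  small_groups <- match.arg(small_groups)
  data <- enforce_min_subgroups(data, min_per_arm, small_groups)
  grp <- data$.risk_group

  rows <- lapply(sort(unique(grp)), function(g) {
    sub <- data[grp == g, ]
    ctrl <- sub[sub$arm == "control", ]
    trt <- sub[sub$arm == "treated", ]
    est <- arr_with_ci(km_estimate(ctrl$time, ctrl$event),
                       km_estimate(trt$time, trt$event),
                       horizon, alpha)
    mutate(est, risk_group = g, .before = 1)
  })
  out <- bind_rows(rows) %>%
    select("risk_group", "n_control", "n_treated", "rate_control",
           "rate_treated", "arr", "se", "arr_lo", "arr_hi")
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Enforce a minimum per-arm subgroup size
#'
#' Kaplan-Meier contrasts in subgroups with very few participants per arm
#' are unstable. This guard either raises an error (default) or repeatedly
#' merges each undersized subgroup into its adjacent lower-risk neighbour
#' (the lowest group merges upward) until every subgroup has at least
#' `min_per_arm` participants in each arm, renumbering groups 1..G.
#'
#' @param data Participant table with `arm` and `.risk_group` columns.
#' @param min_per_arm Minimum participants per arm per subgroup.
#' @param small_groups `"error"` (default) or `"merge"`.
#' @return `data` with arm normalised and `.risk_group` possibly merged and
#'   renumbered.
#' @export
enforce_min_subgroups <- function(data, min_per_arm = 10,
                                  small_groups = c("error", "merge")) {
  small_groups <- match.arg(small_groups)
  .check_participants(data)
  if (!".risk_group" %in% names(data)) abort("no `.risk_group` column; partition first.")
  data <- mutate(as_tibble(data), arm = .normalise_arm(.data$arm))
  grp <- data$.risk_group

  repeat {
    sizes <- table(grp, data$arm)
    small <- rownames(sizes)[apply(sizes, 1, min) < min_per_arm]
    if (length(small) == 0) break
    if (small_groups == "error") {
      abort(paste0("subgroup(s) with fewer than ", min_per_arm,
                   " participants per arm: ", paste(small, collapse = ", "),
                   ". Use small_groups = \"merge\" or enlarge groups."))
    }
    if (length(unique(grp)) <= 1) {
      abort("cannot merge further: a single subgroup remains below the minimum.")
    }
    g <- as.integer(small[1])
    levels_now <- sort(unique(grp))
    target <- if (g == min(levels_now)) levels_now[match(g, levels_now) + 1]
              else levels_now[match(g, levels_now) - 1]
    grp[grp == g] <- target
  }
  data$.risk_group <- match(grp, sort(unique(grp)))  # renumber 1..G
  data
}

#' Number needed to treat from an ARR estimate
#'
#' NNT is the reciprocal of the absolute risk reduction. Its confidence
#' bounds are the order-swapped reciprocals of the ARR bounds, reported only
#' when the ARR interval excludes 0; otherwise the point estimate is
#' returned with non-finite (`NA`) bounds, since a reciprocal interval
#' through 0 is not meaningful.
#'
#' @param estimate A one-row [arr_with_ci()] result or a tibble of
#'   subgroup ARR rows (columns `arr`, `arr_lo`, `arr_hi`).
#' @return The input with `nnt`, `nnt_lo`, `nnt_hi` columns appended.
#' @export
nnt_from_arr <- function(estimate) {
  stopifnot(is.data.frame(estimate),
            all(c("arr", "arr_lo", "arr_hi") %in% names(estimate)))
  if (any(estimate$arr == 0)) abort("NNT undefined where ARR = 0.")
  excludes0 <- estimate$arr_lo > 0 | estimate$arr_hi < 0
  mutate(as_tibble(estimate),
         nnt = 1 / .data$arr,
         nnt_lo = ifelse(excludes0, 1 / .data$arr_hi, NA_real_),
         nnt_hi = ifelse(excludes0, 1 / .data$arr_lo, NA_real_))
}

#' Cochran's Q test for heterogeneity of subgroup ARRs
#'
#' Fixed-effect inverse-variance meta-analysis of the subgroup absolute risk
#' reductions: with weights \eqn{w_g = 1/\mathrm{SE}_g^2} and pooled effect
#' \eqn{\bar\theta = \sum w_g \theta_g / \sum w_g}, the statistic is
#' \eqn{Q = \sum w_g (\theta_g - \bar\theta)^2}, referred to a chi-squared
#' distribution with \eqn{G - 1} degrees of freedom. A significant Q means
#' the treatment's absolute benefit differs across risk subgroups.
#'
#' @param estimates Tibble of subgroup ARR rows with columns `arr` and `se`
#'   (as from [arr_by_subgroup()]).
#' @return An object of class `heterogeneity_test` (scale `"absolute"`).
#' @export
cochran_q <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("arr", "se") %in% names(estimates)))
  G <- nrow(estimates)
  if (G < 2) abort("Cochran's Q needs at least 2 subgroups.")
  if (any(estimates$se <= 0)) abort("every subgroup standard error must be > 0.")
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$arr) / sum(w)
  Q <- sum(w * (estimates$arr - pooled)^2)
  new_heterogeneity_test("absolute", Q, G - 1, pooled = pooled)
}

new_heterogeneity_test <- function(scale, statistic, df, pooled = NA_real_) {
  structure(
    list(scale = scale, statistic = statistic, df = df,
         p_value = pchisq(statistic, df, lower.tail = FALSE),
         pooled = pooled),
    class = "heterogeneity_test"
  )
}

#' @export
print.heterogeneity_test <- function(x, ...) {
  lab <- if (x$scale == "absolute") "Cochran's Q (absolute scale)"
         else "Wald interaction chi-squared (relative scale)"
  cat(sprintf("%s: statistic = %.3f, df = %d, p = %.4g\n",
              lab, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.heterogeneity_test <- function(x, ...) {
  tibble(scale = x$scale, statistic = x$statistic, df = x$df,
         p_value = x$p_value)
}

#' @export
glance.heterogeneity_test <- function(x, ...) tidy(x)

#' Cox interaction test for relative-scale heterogeneity
#'
#' Fits a proportional-hazards regression on treatment arm, subgroup (as a
#' categorical factor), and their interaction, by partial-likelihood
#' maximization with Efron tie handling, and returns the joint Wald
#' chi-squared test on the \eqn{G-1} interaction coefficients. A significant
#' statistic means the hazard ratio for treatment differs across subgroups.
#' Per-subgroup hazard ratios (treated vs control, with Wald confidence
#' intervals) are estimated by separate Cox fits within each subgroup.
#'
#' @param data Participant table with `arm`, `event`, `time`, and a
#'   `.risk_group` column in which every subgroup contains both arms and at
#'   least one event.
#' @param alpha Two-sided significance level for the per-subgroup HR CIs.
#' @return A list of class `cox_hte` with elements `test` (a
#'   `heterogeneity_test`, scale `"relative"`) and `subgroup_hr` (tibble:
#'   `risk_group`, `n`, `events`, `hr`, `hr_lo`, `hr_hi`).
#' @export
cox_interaction_test <- function(data, alpha = 0.05) {
  .check_participants(data)
  if (!".risk_group" %in% names(data)) abort("no `.risk_group` column; partition first.")
  data <- mutate(as_tibble(data), arm = .normalise_arm(.data$arm))
  grp <- factor(data$.risk_group)
  G <- nlevels(grp)
  if (G < 2) abort("interaction not estimable with a single subgroup.")
  bad <- tapply(data$event, grp, sum) == 0 |
    tapply(data$arm == "treated", grp, function(x) !any(x) || all(x))
  if (any(bad)) {
    abort(paste0("subgroup(s) without events or without both arms: ",
                 paste(levels(grp)[bad], collapse = ", ")))
  }

  df_fit <- data.frame(time = data$time, event = data$event,
                       arm = data$arm, grp = grp)
  fit <- survival::coxph(survival::Surv(time, event) ~ arm * grp,
                         data = df_fit, ties = "efron")
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)))) {
    abort("Cox interaction model did not converge to finite coefficients.")
  }
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  ix <- grep(":", names(b), fixed = TRUE)
  stopifnot(length(ix) == G - 1)
  W <- drop(t(b[ix]) %*% solve(V[ix, ix, drop = FALSE]) %*% b[ix])
  test <- new_heterogeneity_test("relative", W, G - 1)

  z <- qnorm(1 - alpha / 2)
  hr <- bind_rows(lapply(levels(grp), function(g) {
    sub <- df_fit[df_fit$grp == g, ]
    f <- survival::coxph(survival::Surv(time, event) ~ arm, data = sub,
                         ties = "efron")
    co <- stats::coef(f)[["armtreated"]]
    se <- sqrt(stats::vcov(f)[1, 1])
    tibble(risk_group = as.integer(g), n = nrow(sub),
           events = sum(sub$event), hr = exp(co),
           hr_lo = exp(co - z * se), hr_hi = exp(co + z * se))
  }))
  structure(list(test = test, subgroup_hr = hr), class = "cox_hte")
}

#' @export
print.cox_hte <- function(x, ...) {
  print(x$test)
  print(x$subgroup_hr)
  invisible(x)
}

#' @export
tidy.cox_hte <- function(x, ...) x$subgroup_hr

#' @export
glance.cox_hte <- function(x, ...) tidy(x$test)

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), surv = c(1, object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years", y = "Survival probability") +
    ggplot2::ylim(0, 1)
}
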