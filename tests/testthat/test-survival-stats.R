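test_that("Kaplan-Meier reduces to empirical survival without censoring", {
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, 4:1)
  # Greenwood variance equals the binomial form S(1-S)/n while S > 0
  expect_equal(km$var[1:3], km$surv[1:3] * (1 - km$surv[1:3]) / 4)
  expect_equal(km$var[4], 0)
})

test_that("censoring shrinks risk sets per the hand product-limit", {
  # subjects: censored at 1, event at 2, censored at 3, event at 4
  km <- km_estimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(km$time, c(2, 4))
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km$n_risk, c(3L, 1L))
})

test_that("an all-censored sample keeps survival at 1 with zero variance", {
  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km), 0)
  r <- event_rate_at(km, 2)
  expect_equal(r$rate, 0)
  expect_equal(r$var, 0)
})

test_that("estimates agree with survival::survfit on censored data", {
  withr::with_seed(31, {
    time <- round(rexp(80, 0.2), 2) + 0.01
    event <- rbinom(80, 1, 0.6)
  })
  km <- km_estimate(time, event)
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1))
  ev <- sf$n.event > 0
  expect_equal(km$time, sf$time[ev])
  expect_equal(km$surv, sf$surv[ev])
  pos <- km$surv > 0  # survfit reports NaN std.err where S reaches 0
  expect_equal(sqrt(km$var)[pos], sf$std.err[ev][pos], tolerance = 1e-8)
})

test_that("event rates read off the curve at the horizon", {
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(event_rate_at(km, 0.5)$rate, 0)
  expect_equal(event_rate_at(km, 2.5)$rate, 0.5)
  rates <- vapply(c(0.5, 1, 2, 2.5, 3, 4), function(t)
    event_rate_at(km, t)$rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  # beyond the last observed time: last estimate, flagged
  expect_warning(r <- event_rate_at(km, 99), "exceeds")
  expect_true(r$extrapolated)
  expect_equal(r$rate, 1)
})

test_that("ARR equals the difference of binomial proportions without censoring", {
  ctrl <- km_estimate(seq(0.5, 5, length.out = 10),
                      c(rep(1, 4), rep(0, 6)))
  trt <- km_estimate(seq(0.5, 5, length.out = 10),
                     c(rep(1, 2), rep(0, 8)))
  est <- arr_with_ci(ctrl, trt, t = 5)
  expect_equal(est$arr, 0.2)
  expect_equal(est$se, sqrt(0.4 * 0.6 / 10 + 0.2 * 0.8 / 10))
  expect_equal(est$arr_lo, 0.2 - qnorm(0.975) * 0.2)
  expect_equal(est$arr_hi, 0.2 + qnorm(0.975) * 0.2)

  # identical arms: zero ARR, interval symmetric about zero
  same <- arr_with_ci(ctrl, ctrl, t = 5)
  expect_equal(same$arr, 0)
  expect_equal(same$arr_lo, -same$arr_hi)

  # swapping arms flips the sign and mirrors the interval
  flip <- arr_with_ci(trt, ctrl, t = 5)
  expect_equal(flip$arr, -est$arr)
  expect_equal(flip$arr_lo, -est$arr_hi)
  expect_equal(flip$arr_hi, -est$arr_lo)
})

test_that("per-subgroup ARR tables respect the minimum-size guard", {
  dat <- generate_trial(trial_scenario(n_participants = 600, seed = 17,
                                       effect = "constant_hr"))
  tab <- dat$participants
  tab$.risk <- dat$truth$risk5_control
  tab <- quintile_partition(tab, 3)
  arr <- arr_by_subgroup(tab, horizon = 5, min_per_arm = 10)
  expect_equal(nrow(arr), 3)
  expect_equal(arr$arr, arr$rate_control - arr$rate_treated)
  expect_true(all(arr$arr_lo <= arr$arr & arr$arr <= arr$arr_hi))
  expect_equal(sum(arr$n_control + arr$n_treated), 600)

  # too-small groups error by default, merge upward on request
  tiny <- tab
  tiny$.risk_group[1:3] <- 0L
  tiny$.risk_group <- tiny$.risk_group + 1L
  expect_error(arr_by_subgroup(tiny, min_per_arm = 10), "fewer than")
  merged <- enforce_min_subgroups(tiny, min_per_arm = 10,
                                  small_groups = "merge")
  expect_equal(sort(unique(merged$.risk_group)), 1:3)
})

test_that("NNT is the order-swapped reciprocal of the ARR interval", {
  est <- tibble::tibble(arr = 0.5, arr_lo = 0.25, arr_hi = 0.75)
  out <- nnt_from_arr(est)
  expect_equal(out$nnt, 2)
  expect_equal(out$nnt_lo, 1 / 0.75)
  expect_equal(out$nnt_hi, 1 / 0.25)

  # interval through zero: point estimate kept, bounds non-finite
  spans <- tibble::tibble(arr = 0.1, arr_lo = -0.05, arr_hi = 0.25)
  out2 <- nnt_from_arr(spans)
  expect_equal(out2$nnt, 10)
  expect_true(is.na(out2$nnt_lo) && is.na(out2$nnt_hi))
  expect_error(nnt_from_arr(tibble::tibble(arr = 0, arr_lo = -1, arr_hi = 1)),
               "undefined")
})

test_that("Cochran's Q matches the hand-computed fixed-effect statistic", {
  est <- tibble::tibble(arr = c(0.1, 0.3), se = c(0.05, 0.05))
  q <- cochran_q(est)
  expect_equal(q$statistic, 8)
  expect_equal(q$df, 1)
  expect_equal(q$p_value, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(q$p_value, 0.00468, tolerance = 1e-3)
  expect_equal(q$pooled, 0.2)

  # equal effects: Q = 0, p = 1
  flat <- tibble::tibble(arr = rep(0.12, 4), se = c(0.03, 0.05, 0.02, 0.04))
  q0 <- cochran_q(flat)
  expect_equal(q0$statistic, 0)
  expect_equal(q0$p_value, 1)

  # invariant under subgroup reordering
  est5 <- tibble::tibble(arr = c(0.05, 0.1, 0.02, 0.2, 0.08),
                         se = c(0.03, 0.02, 0.05, 0.04, 0.03))
  expect_equal(cochran_q(est5)$statistic,
               cochran_q(est5[5:1, ])$statistic)

  expect_error(cochran_q(est[1, ]), "at least 2")
  expect_error(cochran_q(tibble::tibble(arr = c(0, 1), se = c(0, 1))), "> 0")
})

test_that("Cox interaction test keeps its size under a common hazard ratio", {
  sc <- trial_scenario(n_participants = 4000, effect = "constant_hr",
                       effect_params = list(log_hr = -0.3), seed = 1)
  sc$baseline_scale <- calibrate_baseline_scale(sc)
  hits <- 0L
  for (r in 1:100) {
    sc$seed <- 1000L + r
    tr <- generate_trial(sc)
    dat <- tr$participants
    dat$.risk <- tr$truth$risk5_control
    dat <- quintile_partition(dat, 5)
    ct <- suppressWarnings(cox_interaction_test(dat))
    hits <- hits + (ct$test$p_value > 0.05)
    if (r == 1) {
      expect_equal(ct$test$df, 4)
      expect_true(all(ct$subgroup_hr$hr > 0))
      expect_equal(nrow(ct$subgroup_hr), 5)
    }
  }
  expect_gte(hits, 90)
})

test_that("Cox interaction test detects opposite subgroup effects", {
  # two subgroups with true HR 0.5 and 2.0
  withr::with_seed(99, {
    n <- 4000
    grp <- rep(1:2, each = n / 2)
    arm <- rep(c("control", "treated"), times = n / 2)
    hr <- ifelse(grp == 1, 0.5, 2.0)
    rate <- 0.05 * ifelse(arm == "treated", hr, 1)
    t_event <- rexp(n, rate)
    dat <- tibble::tibble(
      id = seq_len(n), arm = arm,
      time = pmin(t_event, 7),
      event = as.integer(t_event <= 7),
      .risk_group = grp
    )
  })
  ct <- cox_interaction_test(dat)
  expect_lt(ct$test$p_value, 0.001)
  expect_lt(ct$subgroup_hr$hr[1], 1)
  expect_gt(ct$subgroup_hr$hr[2], 1)

  one <- dat
  one$.risk_group <- 1L
  expect_error(cox_interaction_test(one), "single subgroup")
})
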