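# shared fixtures and independent oracles, all built in code

# small participant table with a risk-graded binary outcome
toy_participants <- function(n = 100, n_events = 10, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      arm = factor(rep(c("control", "treated"), length.out = n),
                   levels = c("control", "treated")),
      event = c(rep(1L, n_events), rep(0L, n - n_events))[sample.int(n)],
      time = runif(n, 0.5, 7),
      x1 = rnorm(n),
      x2 = rbinom(n, 1, 0.4)
    )
  })
}

# scenario with a single zero-coefficient covariate: lp identically 0
flat_scenario <- function(n = 500, shape = 1, horizon = 7, target = 0.10,
                          dropout = 0, seed = 1, effect = "null", ...) {
  trial_scenario(
    n_participants = n,
    covariates = cov_continuous("z1"),
    risk_coefficients = c(z1 = 0),
    baseline_shape = shape,
    horizon = horizon,
    dropout_rate = dropout,
    target_event_fraction = target,
    effect = effect,
    seed = seed,
    ...
  )
}

# brute-force product-limit oracle: direct recounting at each event time,
# independent of the package's cumulative implementation
brute_km_surv <- function(time, event, t0) {
  s <- 1
  for (tt in sort(unique(time[event == 1 & time <= t0]))) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
  }
  s
}

brute_km_var <- function(time, event, t0) {
  s <- brute_km_surv(time, event, t0)
  if (s == 0) return(0)
  acc <- 0
  for (tt in sort(unique(time[event == 1 & time <= t0]))) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    if (at_risk > d) acc <- acc + d / (at_risk * (at_risk - d))
  }
  s^2 * acc
}

# Mann-Whitney concordance between by-horizon cases and controls
mann_whitney_auc <- function(case_scores, control_scores) {
  cmp <- outer(case_scores, control_scores, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}
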