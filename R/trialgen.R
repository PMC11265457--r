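#' Covariate specification helpers for simulated trials
#'
#' Build entries of the covariate specification used by [trial_scenario()].
#' Continuous covariates are drawn from a normal distribution, binary
#' covariates from a Bernoulli, and categorical covariates from a discrete
#' distribution over named levels (dummy-coded against the first level when
#' they enter the linear predictor; coefficients are keyed `"name.level"`).
#'
#' @param name Column name of the covariate.
#' @param mean,sd Normal parameters (continuous).
#' @param prevalence Probability of a 1 (binary).
#' @param levels,probs Level labels and sampling probabilities (categorical).
#' @return A one-row specification tibble.
#' @export
cov_continuous <- function(name, mean = 0, sd = 1) {
  tibble(name = name, kind = "continuous",
         params = list(list(mean = mean, sd = sd)))
}

#' @rdname cov_continuous
#' @export
cov_binary <- function(name, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  tibble(name = name, kind = "binary",
         params = list(list(prevalence = prevalence)))
}

#' @rdname cov_continuous
#' @export
cov_categorical <- function(name, levels, probs) {
  stopifnot(length(levels) == length(probs), all(probs > 0))
  tibble(name = name, kind = "categorical",
         params = list(list(levels = levels, probs = probs / sum(probs))))
}

#' Default covariate panel for the synthetic trial
#'
#' Ten baseline covariates: six continuous standard-normal measurements and
#' four binary risk factors with prevalences typical of an elderly
#' primary-prevention cohort (0.50, 0.35, 0.20, 0.15).
#'
#' @return A covariate specification tibble.
#' @export
default_covariates <- function() {
  bind_rows(
    purrr::map(paste0("z", 1:6), cov_continuous),
    cov_binary("b1", 0.50),
    cov_binary("b2", 0.35),
    cov_binary("b3", 0.20),
    cov_binary("b4", 0.15)
  )
}

#' Default log-hazard-ratio coefficients for the synthetic trial
#'
#' Per-unit log hazard ratios spanning 0 to 0.5 across the default covariate
#' panel, so that baseline risk is clearly graded across participants.
#'
#' @return A named numeric vector.
#' @export
default_risk_coefficients <- function() {
  c(z1 = 0.5, z2 = 0.4, z3 = 0.3, z4 = 0.2, z5 = 0.1, z6 = 0.0,
    b1 = 0.45, b2 = 0.30, b3 = 0.15, b4 = 0.05)
}

#' Define a synthetic randomized-trial scenario
#'
#' A scenario fixes everything the simulator needs: cohort size and
#' allocation, the covariate panel and its log-hazard-ratio coefficients, a
#' Weibull proportional-hazards event-time model, the treatment-effect
#' structure, the censoring pattern, and a target cumulative event fraction
#' that the baseline scale is calibrated to hit.
#'
#' Treatment-effect modes:
#' \describe{
#'   \item{`"null"`}{no treatment effect (hazard ratio 1 for everyone).}
#'   \item{`"constant_hr"`}{one common log hazard ratio
#'     (`effect_params$log_hr`) for all participants: no relative-scale
#'     heterogeneity, but the absolute risk reduction still grows with
#'     baseline risk.}
#'   \item{`"risk_graded"`}{the treatment log hazard ratio is a linear
#'     function of the participant's latent risk percentile
#'     \eqn{p \in [0,1]}: `theta0 + theta1 * p`. The default
#'     (0.2, -1.0) concentrates benefit in the highest-risk fifth while
#'     lower-risk participants get essentially none.}
#' }
#'
#' @param n_participants Cohort size.
#' @param allocation_ratio Fraction assigned to the treated arm, in (0,1).
#' @param covariates Covariate specification tibble (see [cov_continuous()]).
#' @param risk_coefficients Named log-hazard-ratio vector; names must refer to
#'   covariates (dummy levels as `"name.level"`). Covariates without a named
#'   coefficient carry coefficient 0.
#' @param baseline_shape Weibull shape (>0); 1 gives exponential times.
#' @param baseline_scale Weibull scale in years, or `NA` to calibrate it so
#'   the expected observed-event fraction matches `target_event_fraction`.
#' @param effect Treatment-effect mode.
#' @param effect_params Parameters of the effect mode (see Details).
#' @param horizon Administrative censoring horizon in years.
#' @param dropout_rate Rate (per year) of independent exponential dropout;
#'   0 disables random censoring.
#' @param target_event_fraction Target fraction of participants with an
#'   observed event, in (0,1).
#' @param seed Integer seed; the simulator is fully deterministic given the
#'   scenario (including this seed).
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(n_participants = 2291,
                           allocation_ratio = 0.5,
                           covariates = default_covariates(),
                           risk_coefficients = default_risk_coefficients(),
                           baseline_shape = 1,
                           baseline_scale = NA_real_,
                           effect = c("null", "constant_hr", "risk_graded"),
                           effect_params = NULL,
                           horizon = 7,
                           dropout_rate = 0,
                           target_event_fraction = 0.105,
                           seed = 1L) {
  effect <- match.arg(effect)
  if (n_participants < 2) abort("`n_participants` must be at least 2.")
  if (!(allocation_ratio > 0 && allocation_ratio < 1)) {
    abort("`allocation_ratio` must lie strictly in (0, 1).")
  }
  if (baseline_shape <= 0) abort("Weibull `baseline_shape` must be > 0.")
  if (horizon <= 0) abort("`horizon` must be > 0 years.")
  if (!(target_event_fraction > 0 && target_event_fraction < 1)) {
    abort("`target_event_fraction` must lie strictly in (0, 1).")
  }
  if (dropout_rate < 0) abort("`dropout_rate` must be >= 0.")
  if (nrow(covariates) == 0) abort("`covariates` must not be empty.")
  if (length(risk_coefficients) > 0) {
    if (is.null(names(risk_coefficients)) || any(names(risk_coefficients) == "")) {
      abort("`risk_coefficients` must be a named vector.")
    }
    if (!all(is.finite(risk_coefficients))) {
      abort("`risk_coefficients` must all be finite.")
    }
  }
  effect_params <- switch(
    effect,
    null = list(),
    constant_hr = utils::modifyList(list(log_hr = -0.25),
                                    effect_params %||% list()),
    risk_graded = utils::modifyList(list(theta0 = 0.2, theta1 = -1.0),
                                    effect_params %||% list())
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      allocation_ratio = allocation_ratio,
      covariates = covariates,
      risk_coefficients = risk_coefficients,
      baseline_shape = baseline_shape,
      baseline_scale = baseline_scale,
      effect = effect,
      effect_params = effect_params,
      horizon = horizon,
      dropout_rate = dropout_rate,
      target_event_fraction = target_event_fraction,
      seed = as.integer(seed)
    ),
    class = "trial_scenario"
  )
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("<trial_scenario>\n")
  cat(sprintf("  n = %d, treated fraction = %.2f, seed = %d\n",
              x$n_participants, x$allocation_ratio, x$seed))
  cat(sprintf("  Weibull(shape = %.3g, scale = %s), horizon = %g y, dropout = %.3g /y\n",
              x$baseline_shape,
              if (is.na(x$baseline_scale)) "calibrated" else
                sprintf("%.3g", x$baseline_scale),
              x$horizon, x$dropout_rate))
  cat(sprintf("  effect = %s (%s); target event fraction = %.3f\n",
              x$effect,
              paste(names(x$effect_params), unlist(x$effect_params),
                    sep = "=", collapse = ", "),
              x$target_event_fraction))
  invisible(x)
}

# treatment log hazard ratio as a function of risk percentile in [0, 1]
.treatment_log_hr <- function(scenario, pct) {
  switch(scenario$effect,
         null = rep(0, length(pct)),
         constant_hr = rep(scenario$effect_params$log_hr, length(pct)),
         risk_graded = scenario$effect_params$theta0 +
           scenario$effect_params$theta1 * pct)
}

# draw covariates / linear predictor / arm; all randomness inside the caller's
# seed context so that generate_trial() and calibrate_baseline_scale() agree
.draw_cohort <- function(scenario) {
  n <- scenario$n_participants
  spec <- scenario$covariates
  cols <- list()
  for (i in seq_len(nrow(spec))) {
    p <- spec$params[[i]]
    cols[[spec$name[i]]] <- switch(
      spec$kind[i],
      continuous = rnorm(n, p$mean, p$sd),
      binary = rbinom(n, 1L, p$prevalence),
      categorical = factor(sample(p$levels, n, replace = TRUE, prob = p$probs),
                           levels = p$levels),
      abort(paste0("unknown covariate kind: ", spec$kind[i]))
    )
  }
  covs <- as_tibble(cols)

  coefs <- scenario$risk_coefficients
  lp <- rep(0, n)
  for (nm in names(coefs)) {
    if (nm %in% names(covs)) {
      lp <- lp + coefs[[nm]] * as.numeric(covs[[nm]])
    } else if (grepl(".", nm, fixed = TRUE)) {
      base <- sub("\\.[^.]+$", "", nm)
      lev <- sub("^.*\\.", "", nm)
      if (!base %in% names(covs)) {
        abort(paste0("coefficient `", nm, "` refers to no covariate."))
      }
      lp <- lp + coefs[[nm]] * (as.character(covs[[base]]) == lev)
    } else {
      abort(paste0("coefficient `", nm, "` refers to no covariate."))
    }
  }
  pct <- (rank(lp, ties.method = "average") - 0.5) / n

  n_treated <- round(n * scenario$allocation_ratio)
  arm <- rep("control", n)
  arm[sample.int(n, n_treated)] <- "treated"

  list(covariates = covs, lp = lp, pct = pct,
       arm = factor(arm, levels = c("control", "treated")))
}

# expected fraction of participants with an observed event under a candidate
# Weibull scale; closed form without dropout, quadrature with it
.expected_event_fraction <- function(eta, shape, scale, horizon, dropout_rate) {
  event_cdf <- function(t) mean(1 - exp(-(t / scale)^shape * exp(eta)))
  if (dropout_rate == 0) return(event_cdf(horizon))
  # P(T <= min(C, horizon)) by parts: the integrand is bounded by the
  # dropout density, so no spike at extreme candidate scales
  f <- function(t) vapply(t, function(tt)
    event_cdf(tt) * dropout_rate * exp(-dropout_rate * tt), numeric(1))
  integrate(f, 0, horizon, rel.tol = 1e-9)$value +
    event_cdf(horizon) * exp(-dropout_rate * horizon)
}

#' Calibrate the Weibull baseline scale to a target event fraction
#'
#' Finds the Weibull scale (years) at which the expected fraction of
#' participants with an observed event — under the scenario's covariates,
#' treatment effect, administrative horizon, and dropout — matches
#' `target_event_fraction` to within 0.005, by monotone root search on the
#' scenario's exact expected cumulative incidence (closed form without
#' dropout, numerical integration with it). Covariates and arms are redrawn
#' from the scenario seed, so the result is deterministic and identical to
#' the scale [generate_trial()] uses internally.
#'
#' @param scenario A [trial_scenario()].
#' @return The calibrated scale in years.
#' @export
calibrate_baseline_scale <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  cohort <- .with_seed(scenario$seed, .draw_cohort(scenario))
  .calibrate_scale(scenario, cohort)
}

.calibrate_scale <- function(scenario, cohort) {
  eta <- cohort$lp +
    (cohort$arm == "treated") * .treatment_log_hr(scenario, cohort$pct)
  target <- scenario$target_event_fraction
  g <- function(log_scale) {
    .expected_event_fraction(eta, scenario$baseline_shape, exp(log_scale),
                             scenario$horizon, scenario$dropout_rate) - target
  }
  lo <- log(1e-4); hi <- log(1e8)
  if (g(lo) < 0 || g(hi) > 0) {
    abort("target event fraction unattainable under this censoring spec.")
  }
  root <- uniroot(g, c(lo, hi), tol = 1e-10)
  scale <- exp(root$root)
  achieved <- .expected_event_fraction(eta, scenario$baseline_shape, scale,
                                       scenario$horizon, scenario$dropout_rate)
  if (abs(achieved - target) > 0.005) {
    abort("baseline-scale calibration did not reach the target tolerance.")
  }
  scale
}

#' Generate a synthetic randomized trial
#'
#' Simulates a two-arm trial under a Weibull proportional-hazards model:
#' hazard \eqn{h_0(t)\,\exp(lp + \mathrm{arm} \cdot \log\mathrm{HR}(p))},
#' where `lp` is the covariate linear predictor and `p` its percentile rank.
#' Observed time is the minimum of the event time, random dropout, and the
#' administrative horizon; the event indicator is set accordingly. The
#' baseline scale is calibrated to the target event fraction unless fixed in
#' the scenario. Fully deterministic given the scenario (including its seed).
#'
#' The returned object carries, next to the participant table, a `truth`
#' table with the per-participant latent linear predictor, risk percentile,
#' and true 5-year event risk under each arm — the oracle used in
#' parameter-recovery experiments.
#'
#' @param scenario A [trial_scenario()].
#' @return An object of class `simulated_trial`: a list with tibbles
#'   `participants` and `truth`, plus the scenario augmented with the
#'   realized `baseline_scale`.
#' @export
generate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  .with_seed(scenario$seed, {
    cohort <- .draw_cohort(scenario)
    n <- scenario$n_participants
    scale <- scenario$baseline_scale
    if (is.na(scale)) scale <- .calibrate_scale(scenario, cohort)

    log_hr <- .treatment_log_hr(scenario, cohort$pct)
    eta <- cohort$lp + (cohort$arm == "treated") * log_hr
    shape <- scenario$baseline_shape

    # inverse-CDF draw: S(t) = exp(-(t/scale)^shape * e^eta)
    u <- runif(n)
    t_event <- scale * (-log(u) / exp(eta))^(1 / shape)
    t_cens <- rep(scenario$horizon, n)
    if (scenario$dropout_rate > 0) {
      t_cens <- pmin(t_cens, rexp(n, scenario$dropout_rate))
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    id <- sprintf("P%05d", seq_len(n))
    participants <- tibble(
      id = id, arm = cohort$arm, event = event, time = time
    ) %>% dplyr::bind_cols(cohort$covariates)

    h5 <- (5 / scale)^shape
    truth <- tibble(
      id = id,
      lp = cohort$lp,
      risk_pct = cohort$pct,
      log_hr_treated = log_hr,
      risk5_control = 1 - exp(-h5 * exp(cohort$lp)),
      risk5_treated = 1 - exp(-h5 * exp(cohort$lp + log_hr))
    )

    out <- scenario
    out$baseline_scale <- scale
    structure(
      list(participants = participants, truth = truth, scenario = out),
      class = "simulated_trial"
    )
  })
}

#' @export
print.simulated_trial <- function(x, ...) {
  p <- x$participants
  cat("<simulated_trial>\n")
  cat(sprintf("  %d participants (%d treated), %d events (%.1f%%), scale = %.2f y\n",
              nrow(p), sum(p$arm == "treated"), sum(p$event),
              100 * mean(p$event), x$scenario$baseline_scale))
  invisible(x)
}

#' True subgroup-level absolute risk reduction
#'
#' Forms `n_groups` ordered groups by rank of the true 5-year control-arm
#' risk and returns, for each group, the mean true control-arm risk, mean
#' true treated-arm risk, and their difference (the true ARR). This is the
#' oracle against which estimated subgroup effects are checked.
#'
#' @param trial A [generate_trial()] result.
#' @param n_groups Number of ordered risk groups.
#' @return A tibble with one row per risk group.
#' @export
true_arr_by_risk_group <- function(trial, n_groups = 5) {
  stopifnot(inherits(trial, "simulated_trial"))
  tr <- trial$truth
  if (n_groups > nrow(tr)) abort("`n_groups` exceeds the number of participants.")
  grp <- .rank_groups(tr$risk5_control, tr$id, n_groups)
  tr %>%
    mutate(risk_group = grp) %>%
    group_by(.data$risk_group) %>%
    summarise(
      n = dplyr::n(),
      true_risk_control = mean(.data$risk5_control),
      true_risk_treated = mean(.data$risk5_treated),
      .groups = "drop"
    ) %>%
    mutate(true_arr = .data$true_risk_control - .data$true_risk_treated)
}

#' The simulated trial's own risk model as a published-score object
#'
#' Packages the simulator's true log-hazard-ratio coefficients and realized
#' baseline survival as a single-stratum [ph_risk_model()] (centering values
#' 0), so the pipeline's extant-score arm can be exercised on synthetic data
#' with a score that is correct by construction. Only continuous and binary
#' covariates are supported (the default panel).
#'
#' @param trial A [generate_trial()] result.
#' @return A `ph_risk_model` whose predictions equal the trial's true
#'   control-arm 5-year risks.
#' @export
true_ph_model <- function(trial) {
  stopifnot(inherits(trial, "simulated_trial"))
  sc <- trial$scenario
  coefs <- sc$risk_coefficients
  if (any(grepl(".", names(coefs), fixed = TRUE) &
          !names(coefs) %in% names(trial$participants))) {
    abort("dummy-coded categorical coefficients are not representable.")
  }
  s0 <- exp(-(5 / sc$baseline_scale)^sc$baseline_shape)
  ph_risk_model(
    coefficients = tibble(
      stratum = "all", covariate = names(coefs),
      coefficient = unname(coefs), center = 0
    ),
    baseline_survival = c(all = s0)
  )
}

#' Read and write trial scenarios as YAML
#'
#' The scenario round-trips through a plain-text YAML file so simulation
#' settings can be version-controlled alongside results.
#'
#' @param scenario A [trial_scenario()].
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a `trial_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "trial_scenario"))
  x <- unclass(scenario)
  x$covariates <- purrr::pmap(scenario$covariates,
                              function(name, kind, params)
                                c(list(name = name, kind = kind), params))
  x$risk_coefficients <- as.list(scenario$risk_coefficients)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  covs <- bind_rows(purrr::map(x$covariates, function(cv) {
    switch(cv$kind,
           continuous = cov_continuous(cv$name, cv$mean %||% 0, cv$sd %||% 1),
           binary = cov_binary(cv$name, cv$prevalence),
           categorical = cov_categorical(cv$name, unlist(cv$levels),
                                         unlist(cv$probs)))
  }))
  trial_scenario(
    n_participants = x$n_participants,
    allocation_ratio = x$allocation_ratio,
    covariates = covs,
    risk_coefficients = unlist(x$risk_coefficients),
    baseline_shape = x$baseline_shape,
    baseline_scale = x$baseline_scale %||% NA_real_,
    effect = x$effect,
    effect_params = x$effect_params,
    horizon = x$horizon,
    dropout_rate = x$dropout_rate,
    target_event_fraction = x$target_event_fraction,
    seed = x$seed
  )
}

#' Write a simulated trial to delimited text
#'
#' Writes the participant table and the truth table as two CSV files with
#' header rows.
#'
#' @param trial A [generate_trial()] result.
#' @param participants_path,truth_path Output CSV paths.
#' @return The trial, invisibly.
#' @export
write_trial <- function(trial, participants_path, truth_path) {
  stopifnot(inherits(trial, "simulated_trial"))
  readr::write_csv(trial$participants, participants_path)
  readr::write_csv(trial$truth, truth_path)
  invisible(trial)
}
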