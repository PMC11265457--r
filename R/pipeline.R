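#' Run the full risk-model-based HTE analysis
#'
#' Orchestrates the four stages of the analysis on a participant table:
#' (1) complete-case filtering and an outcome-stratified 50/50 split, with
#' minority-class oversampling of the training half only; (2) subgroup
#' generation by each requested model — the extant proportional-hazards
#' risk score applied to the full filtered cohort (or, optionally, to the
#' test half only), a bootstrap decision-tree committee, and a
#' probability-weighted random forest, the latter two trained on the
#' augmented training half and subgrouped on the untouched test half;
#' (3) predictive-ability assessment on the test half (threshold metrics,
#' time-dependent AUC at the horizon, per-subgroup calibration); and
#' (4) HTE testing per model: per-subgroup Kaplan-Meier ARR at the horizon
#' with Cochran's Q on the absolute scale, and the Cox interaction Wald
#' test with per-subgroup hazard ratios on the relative scale, plus the NNT
#' for the highest-risk subgroup.
#'
#' All randomness flows from `seed`. Test-half rows never enter
#' oversampling, bootstrap resampling, or hyperparameter tuning; the
#' disjointness is asserted and recorded in the report's provenance block.
#'
#' @param data Participant table (`id`, `arm`, `event`, `time`, covariates).
#' @param models Subset of `c("linear_ph", "tree", "forest")`.
#' @param ph_model A [ph_risk_model()]; required when `"linear_ph"` is
#'   requested.
#' @param ph_stratum Stratum column name for the PH model, if stratified.
#' @param horizon HTE horizon in years (default 5).
#' @param n_groups Number of risk-quintile groups (default 5).
#' @param alpha Two-sided significance level.
#' @param seed Integer seed driving every random step.
#' @param test_fraction Fraction assigned to the test half.
#' @param covariates Covariate columns for the machine-learning models;
#'   default: every column except id/arm/event/time.
#' @param linear_ph_cohort `"full"` (default, the extant model scores the
#'   entire filtered cohort) or `"test"` for an apples-to-apples comparison
#'   restricted to the test half.
#' @param min_per_arm Minimum subgroup size per arm before Kaplan-Meier
#'   contrasts (default 10).
#' @param small_groups `"error"` (default) or `"merge"` undersized
#'   subgroups into their lower-risk neighbour.
#' @param B,tree_max_leaves Committee size and leaf cap for the tree model.
#' @param n_trees,forest_max_leaves,cv_folds Forest size, leaf cap, and
#'   tuning folds.
#' @param tune Cross-validate forest hyperparameters (disable for speed).
#' @return An object of class `hte_report`.
#' @export
run_hte_analysis <- function(data,
                             models = c("linear_ph", "tree", "forest"),
                             ph_model = NULL, ph_stratum = NULL,
                             horizon = 5, n_groups = 5, alpha = 0.05,
                             seed = 1L, test_fraction = 0.5,
                             covariates = NULL,
                             linear_ph_cohort = c("full", "test"),
                             min_per_arm = 10,
                             small_groups = c("error", "merge"),
                             B = 30, tree_max_leaves = 6,
                             n_trees = 100, forest_max_leaves = 10,
                             cv_folds = 10, tune = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  linear_ph_cohort <- match.arg(linear_ph_cohort)
  small_groups <- match.arg(small_groups)
  .check_participants(data)
  if ("linear_ph" %in% models && is.null(ph_model)) {
    abort("`ph_model` is required when the linear_ph model is requested.")
  }
  covariates <- .model_covariates(data, covariates)
  required <- unique(c(covariates,
                       if (!is.null(ph_model)) ph_model$coefficients$covariate,
                       if (!is.null(ph_stratum)) ph_stratum))

  n_input <- nrow(data)
  filtered <- complete_case_filter(data, required)
  split <- stratified_split(filtered, test_fraction, seed = seed)
  train_aug <- oversample_minority(split$train, seed = seed + 1L)
  stopifnot(length(intersect(split$train$id, split$test$id)) == 0,
            all(train_aug$id %in% split$train$id))

  results <- list()
  for (m in models) {
    if (m == "linear_ph") {
      cohort <- if (linear_ph_cohort == "full") filtered else split$test
      scored <- predict_linear_ph_risk(cohort, ph_model, stratum = ph_stratum) %>%
        quintile_partition(n_groups = n_groups)
      test_scored <- predict_linear_ph_risk(split$test, ph_model,
                                            stratum = ph_stratum)
      results[[m]] <- .assess_model(scored, test_scored, horizon, alpha,
                                    min_per_arm, small_groups)
    } else if (m == "tree") {
      committee <- fit_tree_committee(train_aug, split$test,
                                      B = B, max_leaves = tree_max_leaves,
                                      seed = seed + 2L,
                                      covariates = covariates)
      scored <- tree_risk_scores(split$test, committee) %>%
        tree_subgroups(committee)
      results[[m]] <- .assess_model(scored, scored, horizon, alpha,
                                    min_per_arm, small_groups)
      results[[m]]$tuning <- committee$tuning
      results[[m]]$selected_accuracy <- selected_tree_accuracy(committee)
    } else {
      forest <- fit_weighted_forest(train_aug, n_trees = n_trees,
                                    max_leaves = forest_max_leaves,
                                    cv_folds = cv_folds, seed = seed + 3L,
                                    covariates = covariates, tune = tune)
      scored <- forest_risk_scores(split$test, forest) %>%
        quintile_partition(n_groups = n_groups)
      results[[m]] <- .assess_model(scored, scored, horizon, alpha,
                                    min_per_arm, small_groups)
      results[[m]]$tuning <- forest$tuning
    }
  }

  config <- list(models = models, horizon = horizon, n_groups = n_groups,
                 alpha = alpha, seed = seed, test_fraction = test_fraction,
                 linear_ph_cohort = linear_ph_cohort,
                 min_per_arm = min_per_arm, small_groups = small_groups,
                 B = B, tree_max_leaves = tree_max_leaves, n_trees = n_trees,
                 forest_max_leaves = forest_max_leaves, cv_folds = cv_folds,
                 tune = tune, covariates = covariates)
  structure(
    list(
      models = results,
      counts = list(n_input = n_input, n_excluded = n_excluded(filtered),
                    n_analyzed = nrow(filtered), n_train = nrow(split$train),
                    n_test = nrow(split$test),
                    n_train_augmented = nrow(train_aug)),
      provenance = list(config = config, config_hash = rlang::hash(config),
                        seed = seed, leakage_checked = TRUE,
                        package_version = as.character(
                          utils::packageVersion("riskhte")))
    ),
    class = "hte_report"
  )
}

# assessment + HTE testing shared by the three models. `scored` carries the
# subgroup assignment used for HTE; `test_scored` carries the test-half
# scores used for classification metrics and AUC.
.assess_model <- function(scored, test_scored, horizon, alpha,
                          min_per_arm, small_groups) {
  # one consistent grouping for ARR, interaction test, and calibration
  scored <- enforce_min_subgroups(scored, min_per_arm, small_groups)
  arr <- arr_by_subgroup(scored, horizon = horizon, alpha = alpha,
                         min_per_arm = min_per_arm,
                         small_groups = small_groups)
  # NNT is undefined at ARR exactly 0; keep such rows as NA instead of failing
  excl0 <- arr$arr_lo > 0 | arr$arr_hi < 0
  arr <- mutate(arr,
                nnt = ifelse(.data$arr == 0, NA_real_, 1 / .data$arr),
                nnt_lo = ifelse(excl0, 1 / .data$arr_hi, NA_real_),
                nnt_hi = ifelse(excl0, 1 / .data$arr_lo, NA_real_))
  q <- cochran_q(arr)
  cox <- cox_interaction_test(scored, alpha = alpha)
  metrics <- threshold_metrics(binary_outcome_label(test_scored),
                               test_scored$.risk, threshold = 0.5,
                               alpha = alpha)
  auc <- time_dependent_auc(test_scored$time, test_scored$event,
                            test_scored$.risk, horizon = horizon)
  calibration <- calibration_by_subgroup(scored, horizon = horizon)
  list(
    subgroups = subgroup_sizes(scored),
    metrics = metrics,
    auc = auc,
    calibration = calibration,
    arr = arr,
    q_test = q,
    interaction = cox,
    nnt_top = arr[nrow(arr), c("risk_group", "arr", "nnt", "nnt_lo", "nnt_hi")]
  )
}

#' @export
print.hte_report <- function(x, ...) {
  cat("<hte_report>\n")
  with(x$counts, cat(sprintf(
    "  input %d, excluded %d, analyzed %d (train %d / test %d)\n",
    n_input, n_excluded, n_analyzed, n_train, n_test)))
  print(glance(x))
  invisible(x)
}

#' @export
glance.hte_report <- function(x, ...) {
  bind_rows(lapply(names(x$models), function(m) {
    r <- x$models[[m]]
    top <- r$arr[nrow(r$arr), ]
    tibble(model = m, n_subgroups = nrow(r$subgroups),
           accuracy = r$metrics$accuracy, auc = r$auc,
           top_arr = top$arr, top_nnt = top$nnt,
           q_statistic = r$q_test$statistic, q_p = r$q_test$p_value,
           interaction_p = r$interaction$test$p_value)
  }))
}

#' @export
tidy.hte_report <- function(x, ...) {
  bind_rows(lapply(names(x$models), function(m) {
    mutate(x$models[[m]]$arr, model = m, .before = 1)
  }))
}

#' @export
autoplot.hte_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$risk_group),
                                   y = 100 * .data$arr)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = 100 * .data$arr_lo,
                                          ymax = 100 * .data$arr_hi)) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Risk subgroup (1 = lowest risk)",
                  y = "Absolute risk reduction at horizon (%)")
}

#' Participant-flow accounting for a pipeline run
#'
#' Stage counts of the analysis (input, excluded, analyzed, train, test, and
#' per-model subgroup sizes), internally consistent by construction:
#' train + test = input - excluded, and each model's subgroup sizes sum to
#' the size of the set it scored.
#'
#' @param report An [run_hte_analysis()] result.
#' @return A tibble with columns `stage`, `model`, `n`.
#' @export
flow_accounting <- function(report) {
  stopifnot(inherits(report, "hte_report"))
  cn <- report$counts
  base <- tibble(
    stage = c("input", "excluded", "analyzed", "train", "test"),
    model = NA_character_,
    n = c(cn$n_input, cn$n_excluded, cn$n_analyzed, cn$n_train, cn$n_test)
  )
  per_model <- bind_rows(lapply(names(report$models), function(m) {
    sg <- report$models[[m]]$subgroups
    tibble(stage = paste0("subgroup_", sg$risk_group), model = m, n = sg$n)
  }))
  bind_rows(base, per_model)
}

#' Serialize and restore an HTE report
#'
#' Writes the report — counts, per-model tables, heterogeneity tests, and
#' the provenance block — as structured JSON, and reads it back into an
#' `hte_report`. The round trip is lossless up to floating-point text
#' representation.
#'
#' @param report An [run_hte_analysis()] result.
#' @param path JSON file path.
#' @return `write_hte_report()` returns `path` invisibly;
#'   `read_hte_report()` returns an `hte_report`.
#' @export
write_hte_report <- function(report, path) {
  stopifnot(inherits(report, "hte_report"))
  models <- lapply(report$models, function(r) {
    list(subgroups = r$subgroups, metrics = r$metrics, auc = r$auc,
         calibration = r$calibration, arr = r$arr,
         q_test = tidy(r$q_test),
         interaction_test = tidy(r$interaction$test),
         subgroup_hr = r$interaction$subgroup_hr,
         nnt_top = r$nnt_top,
         tuning = r$tuning, selected_accuracy = r$selected_accuracy)
  })
  jsonlite::write_json(
    list(models = models, counts = report$counts,
         provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_hte_report
#' @export
read_hte_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  retibble <- function(df, dbl = character(0)) {
    if (!is.data.frame(df)) return(df)
    df <- as_tibble(df)
    # all-null JSON columns come back logical; restore their numeric type
    for (cl in intersect(dbl, names(df))) df[[cl]] <- as.numeric(df[[cl]])
    df
  }
  models <- lapply(x$models, function(r) {
    qt <- r$q_test
    it <- r$interaction_test
    list(
      subgroups = retibble(r$subgroups), metrics = retibble(r$metrics),
      auc = r$auc, calibration = retibble(r$calibration),
      arr = retibble(r$arr, dbl = c("nnt", "nnt_lo", "nnt_hi")),
      q_test = new_heterogeneity_test(qt$scale, qt$statistic, qt$df),
      interaction = structure(
        list(test = new_heterogeneity_test(it$scale, it$statistic, it$df),
             subgroup_hr = retibble(r$subgroup_hr)),
        class = "cox_hte"),
      nnt_top = retibble(r$nnt_top, dbl = c("nnt", "nnt_lo", "nnt_hi")),
      tuning = retibble(r$tuning),
      selected_accuracy = r$selected_accuracy
    )
  })
  structure(
    list(models = models, counts = x$counts, provenance = x$provenance),
    class = "hte_report"
  )
}

#' Replicated simulation experiment for the heterogeneity tests
#'
#' Repeatedly simulates trials from a scenario, forms risk groups, and runs
#' the absolute-scale Cochran's Q test and (optionally) the relative-scale
#' Cox interaction test on each replicate. Used to study the tests'
#' operating characteristics: type-I error under a null scenario, power
#' under a risk-graded absolute-benefit scenario, and the
#' absolute/relative-scale dissociation under a constant hazard ratio.
#'
#' Risk groups come from the simulator's known truth by default (quintiles
#' of the true control-arm risk), isolating the behaviour of the tests from
#' the behaviour of any fitted risk model.
#'
#' @param scenario A [trial_scenario()]; its Weibull scale is calibrated
#'   once and reused across replicates.
#' @param reps Number of replicate trials.
#' @param seed Integer seed; replicate r uses scenario seed `seed + r`.
#' @param n_groups Number of risk groups.
#' @param horizon Horizon in years.
#' @param alpha Nominal level used for the rejection-rate summary.
#' @param cox Also run the Cox interaction test per replicate.
#' @return A tibble with one row per replicate (`rep`, `q_statistic`,
#'   `q_p`, and if requested `cox_statistic`, `cox_p`), with the
#'   rejection rates at `alpha` in the `rejection` attribute.
#' @export
replicate_hte_experiment <- function(scenario, reps, seed = 1L,
                                     n_groups = 5, horizon = 5,
                                     alpha = 0.05, cox = FALSE) {
  stopifnot(inherits(scenario, "trial_scenario"), reps >= 1)
  scenario$seed <- as.integer(seed)
  if (is.na(scenario$baseline_scale)) {
    scenario$baseline_scale <- calibrate_baseline_scale(scenario)
  }
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    sc <- scenario
    sc$seed <- as.integer(seed + r)
    trial <- generate_trial(sc)
    dat <- trial$participants
    dat$.risk <- trial$truth$risk5_control
    dat <- quintile_partition(dat, n_groups = n_groups)
    arr <- arr_by_subgroup(dat, horizon = horizon, min_per_arm = 2)
    q <- cochran_q(arr)
    row <- tibble(rep = r, q_statistic = q$statistic, q_p = q$p_value)
    if (cox) {
      ct <- cox_interaction_test(dat)
      row$cox_statistic <- ct$test$statistic
      row$cox_p <- ct$test$p_value
    }
    rows[[r]] <- row
  }
  out <- bind_rows(rows)
  rejection <- list(q = mean(out$q_p < alpha))
  if (cox) rejection$cox <- mean(out$cox_p < alpha)
  attr(out, "rejection") <- rejection
  out
}
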