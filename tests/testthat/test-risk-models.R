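simple_ph_model <- function() {
  ph_risk_model(
    coefficients = tibble::tibble(
      stratum = "all", covariate = "x", coefficient = log(2), center = 0),
    baseline_survival = c(all = 0.9)
  )
}

test_that("PH risk predictions follow the closed form 1 - S0^exp(lp)", {
  dat <- tibble::tibble(id = 1:4, x = c(0, 1, 0, 1))

  # null linear predictor: everyone gets 1 - S0(5)
  m0 <- ph_risk_model(
    tibble::tibble(stratum = "all", covariate = "x", coefficient = 0, center = 0),
    c(all = 0.9))
  expect_equal(predict_linear_ph_risk(dat, m0)$.risk, rep(0.1, 4))

  # coefficient ln 2 on a binary covariate: risk 1 - 0.9^2 = 0.19 when x = 1
  r <- predict_linear_ph_risk(dat, simple_ph_model())$.risk
  expect_equal(r[dat$x == 1], rep(0.19, 2))
  expect_equal(r[dat$x == 0], rep(0.1, 2))

  # risk strictly increasing in a positively weighted covariate
  grad <- tibble::tibble(id = 1:9, x = seq(-2, 2, by = 0.5))
  expect_true(all(diff(predict_linear_ph_risk(grad, simple_ph_model())$.risk) > 0))
})

test_that("stratified PH models route participants to their stratum", {
  m <- ph_risk_model(
    tibble::tibble(stratum = c("f", "m"), covariate = "x",
                   coefficient = c(0.5, 1.0), center = c(1, 2)),
    c(f = 0.95, m = 0.85))
  dat <- tibble::tibble(id = 1:2, sex = c("f", "m"), x = c(1, 2))
  r <- predict_linear_ph_risk(dat, m, stratum = "sex")$.risk
  expect_equal(r, c(1 - 0.95, 1 - 0.85))  # centered lp = 0 in both strata

  expect_error(predict_linear_ph_risk(
    tibble::tibble(id = 1, sex = "x", x = 1), m, stratum = "sex"), "absent")
  expect_error(predict_linear_ph_risk(tibble::tibble(id = 1, sex = "f"), m,
                                      stratum = "sex"), "missing")
})

test_that("coefficient tables round-trip exactly through CSV", {
  m <- ph_risk_model(
    tibble::tibble(stratum = rep(c("f", "m"), each = 2),
                   covariate = rep(c("age", "sbp"), 2),
                   coefficient = c(0.031, 0.0042, 0.054, 0.0061),
                   center = c(75, 139, 74, 133)),
    c(f = 0.937, m = 0.912))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ph_risk_model(m, path)
  m2 <- read_ph_risk_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$baseline_survival, m$baseline_survival)
})

test_that("rank partition cuts 1,150 scores into five groups of 230", {
  dat <- withr::with_seed(1, tibble::tibble(id = 1:1150, .risk = runif(1150)))
  out <- quintile_partition(dat)
  expect_equal(subgroup_sizes(out)$n, rep(230L, 5))
  # group index increases with score
  means <- tapply(out$.risk, out$.risk_group, mean)
  expect_true(all(diff(means) > 0))
})

test_that("rank partition handles edge sizes, ties, and monotone transforms", {
  # n = G: each participant its own group, ordered by score
  d5 <- tibble::tibble(id = 1:5, .risk = c(0.3, 0.1, 0.5, 0.2, 0.4))
  expect_equal(quintile_partition(d5, 5)$.risk_group, c(3L, 1L, 5L, 2L, 4L))

  # all scores tied: deterministic assignment by id order, equal sizes
  tied <- tibble::tibble(id = sprintf("a%02d", 1:10), .risk = 0.5)
  g <- quintile_partition(tied, 5)$.risk_group
  expect_equal(g, rep(1:5, each = 2))

  # invariance under strictly monotone score transforms
  dat <- withr::with_seed(2, tibble::tibble(id = 1:97, .risk = rnorm(97)))
  base <- quintile_partition(dat, 4)$.risk_group
  for (f in list(exp, function(x) 3 * x - 10, function(x) x^3)) {
    alt <- dat
    alt$.risk <- f(dat$.risk)
    expect_identical(quintile_partition(alt, 4)$.risk_group, base)
  }

  # uneven n: sizes differ by at most 1, larger blocks at higher groups
  d12 <- tibble::tibble(id = 1:12, .risk = runif(12))
  expect_equal(subgroup_sizes(quintile_partition(d12, 5))$n,
               c(2L, 2L, 2L, 3L, 3L))
  expect_error(quintile_partition(d5, 0), "at least 1")
  expect_error(quintile_partition(d5, 6), "fewer participants")
})

# separable training data: outcome is exactly x > 0
separable_data <- function(n, seed = 1) {
  withr::with_seed(seed, {
    x <- runif(n, -1, 1)
    tibble::tibble(id = seq_len(n), arm = "control",
                   event = as.integer(x > 0),
                   time = runif(n, 1, 7), x = x,
                   noise = rnorm(n))
  })
}

test_that("a single-tree committee selects its only tree", {
  train <- separable_data(200)
  test <- separable_data(100, seed = 2)
  cm <- fit_tree_committee(train, test, B = 1, seed = 1,
                           minbucket_grid = c(10))
  expect_equal(cm$selected, 1L)
  expect_equal(length(cm$trees), 1L)
})

test_that("the committee recovers a separable decision boundary", {
  train <- separable_data(400)
  test <- separable_data(200, seed = 3)
  cm <- fit_tree_committee(train, test, B = 5, seed = 9,
                           minbucket_grid = c(10, 20))
  tree <- cm$trees[[cm$selected]]
  first_split <- tree$splits[1, "index"]
  expect_lt(abs(first_split), 0.15)
  expect_gte(selected_tree_accuracy(cm), 0.95)
})

test_that("the selected tree realizes the lower-median accuracy", {
  train <- toy_participants(300, n_events = 120, seed = 5)
  test <- toy_participants(150, n_events = 60, seed = 6)
  cm <- fit_tree_committee(train, test, B = 6, seed = 2,
                           minbucket_grid = c(15))
  expect_equal(selected_tree_accuracy(cm),
               sort(cm$accuracy)[ceiling(cm$B / 2)])
  expect_length(cm$accuracy, cm$B)
  # every tree respects the leaf cap
  expect_true(all(cm$tuning$n_leaves <= cm$max_leaves))
})

test_that("committee fits are deterministic given the seed", {
  train <- separable_data(200)
  test <- separable_data(100, seed = 2)
  a <- fit_tree_committee(train, test, B = 3, seed = 4, minbucket_grid = 10)
  b <- fit_tree_committee(train, test, B = 3, seed = 4, minbucket_grid = 10)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$selected, b$selected)
})

test_that("tree subgroups partition the table with risk-ordered leaves", {
  train <- separable_data(400)
  test <- separable_data(333, seed = 7)
  cm <- fit_tree_committee(train, test, B = 3, seed = 1, minbucket_grid = 20)
  out <- tree_subgroups(test, cm)
  sizes <- subgroup_sizes(out)
  expect_equal(sum(sizes$n), nrow(test))
  leaves <- attr(out, "leaves")
  expect_true(all(diff(leaves$train_event_prob) >= 0))
  # observed event proportions follow the leaf ordering on held-out data
  obs <- tapply(out$event, out$.risk_group, mean)
  expect_true(all(diff(obs) >= 0))
})

test_that("a stump-less tree puts everyone in group 1", {
  # pure noise with a huge minimum leaf forces a single-leaf tree
  dat <- toy_participants(80, n_events = 40, seed = 9)
  cm <- fit_tree_committee(dat, dat, B = 1, seed = 1,
                           minbucket_grid = c(200))
  out <- tree_subgroups(dat, cm)
  expect_true(all(out$.risk_group == 1L))
})

test_that("forest probabilities are valid, deterministic, and aggregate by mean", {
  train <- toy_participants(300, n_events = 150, seed = 11)
  f1 <- fit_weighted_forest(train, n_trees = 30, seed = 3, tune = FALSE)
  f2 <- fit_weighted_forest(train, n_trees = 30, seed = 3, tune = FALSE)
  sc1 <- forest_risk_scores(train, f1)$.risk
  expect_true(all(sc1 >= 0 & sc1 <= 1))
  expect_identical(sc1, forest_risk_scores(train, f2)$.risk)

  # identical participants receive identical scores
  twin <- train[c(1, 1), ]
  tw <- forest_risk_scores(twin, f1)$.risk
  expect_equal(tw[1], tw[2])

  # ensemble prediction is the mean of per-tree leaf probabilities
  x <- train[1:20, c("x1", "x2")]
  all_trees <- predict(f1$forest, as.data.frame(x), predict.all = TRUE)
  expect_equal(unname(all_trees$aggregate),
               unname(rowMeans(all_trees$individual)))
  one <- fit_weighted_forest(train, n_trees = 1, seed = 5, tune = FALSE)
  single <- predict(one$forest, as.data.frame(x), predict.all = TRUE)
  expect_equal(unname(single$aggregate), unname(single$individual[, 1]))
})

test_that("forest scores are uninformative on pure-noise labels", {
  dat <- withr::with_seed(21, tibble::tibble(
    id = 1:1600, arm = "control",
    event = rbinom(1600, 1, 0.5), time = runif(1600, 1, 7),
    x1 = rnorm(1600), x2 = rnorm(1600), x3 = rnorm(1600)
  ))
  train <- dat[1:800, ]
  test <- dat[801:1600, ]
  f <- fit_weighted_forest(train, n_trees = 60, seed = 7, tune = FALSE)
  sc <- forest_risk_scores(test, f)$.risk
  auc <- mann_whitney_auc(sc[test$event == 1], sc[test$event == 0])
  expect_gte(auc, 0.45)
  expect_lte(auc, 0.55)
})

test_that("forest scores track true risk in a risk-graded simulation", {
  tr <- generate_trial(trial_scenario(n_participants = 2000,
                                      effect = "risk_graded", seed = 13))
  sp <- stratified_split(tr$participants, 0.5, seed = 1)
  aug <- oversample_minority(sp$train, seed = 2)
  f <- fit_weighted_forest(aug, n_trees = 80, seed = 3, tune = FALSE)
  scored <- forest_risk_scores(sp$test, f)
  truth <- tr$truth$risk5_control[match(scored$id, tr$truth$id)]
  expect_gt(cor(scored$.risk, truth, method = "spearman"), 0.3)

  # mean true risk is nondecreasing across quintiles for both score types
  q_forest <- quintile_partition(scored)
  m_forest <- tapply(truth, q_forest$.risk_group, mean)
  expect_true(all(diff(m_forest) >= 0))
  phm <- true_ph_model(tr)
  q_ph <- quintile_partition(predict_linear_ph_risk(sp$test, phm))
  m_ph <- tapply(truth, q_ph$.risk_group, mean)
  expect_true(all(diff(m_ph) >= 0))
})

test_that("forest hyperparameter tuning records the cross-validation grid", {
  train <- toy_participants(200, n_events = 100, seed = 15)
  f <- fit_weighted_forest(train, n_trees = 20, cv_folds = 4, seed = 1,
                           tune = TRUE)
  expect_true(all(c("mtry", "nodesize", "cv_accuracy") %in% names(f$tuning)))
  expect_true(all(f$tuning$cv_accuracy >= 0 & f$tuning$cv_accuracy <= 1))
  expect_equal(f$mtry, f$tuning$mtry[f$chosen])
  expect_error(fit_weighted_forest(train, n_trees = 0), "n_trees")
})
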