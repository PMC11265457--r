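#' Stratified linear proportional-hazards risk model
#'
#' Container for an externally published PH risk score: per stratum (for
#' example, one model per sex) a set of log-hazard-ratio coefficients with
#' centering values, plus the stratum's 5-year baseline survival
#' \eqn{S_0(5)}. Predicted 5-year risk for a participant in stratum *s* is
#' \deqn{1 - S_0(5)_s^{\exp(lp)}, \quad lp = \sum_j \beta_{sj}(x_j - c_{sj}).}
#'
#' @param coefficients Tibble with columns `stratum`, `covariate`,
#'   `coefficient`, `center`.
#' @param baseline_survival Named numeric vector of \eqn{S_0(5)} per stratum,
#'   each in (0,1).
#' @return An object of class `ph_risk_model`.
#' @export
ph_risk_model <- function(coefficients, baseline_survival) {
  coefficients <- as_tibble(coefficients)
  needed <- c("stratum", "covariate", "coefficient", "center")
  if (!all(needed %in% names(coefficients))) {
    abort("`coefficients` needs columns stratum, covariate, coefficient, center.")
  }
  if (!all(is.finite(coefficients$coefficient))) {
    abort("every coefficient must be finite.")
  }
  strata <- unique(coefficients$stratum)
  if (is.null(names(baseline_survival)) ||
      !setequal(names(baseline_survival), strata)) {
    abort("`baseline_survival` must be named with exactly the model's strata.")
  }
  if (!all(baseline_survival > 0 & baseline_survival < 1)) {
    abort("baseline survival S0(5) must lie strictly in (0, 1).")
  }
  structure(
    list(coefficients = coefficients,
         baseline_survival = baseline_survival[strata],
         strata = strata),
    class = "ph_risk_model"
  )
}

#' @export
print.ph_risk_model <- function(x, ...) {
  cat("<ph_risk_model>\n")
  for (s in x$strata) {
    k <- sum(x$coefficients$stratum == s)
    cat(sprintf("  stratum %s: %d coefficients, S0(5) = %.4f\n",
                s, k, x$baseline_survival[[s]]))
  }
  invisible(x)
}

#' Read and write a PH risk model as a coefficient table
#'
#' The delimited-text format has columns `stratum, covariate, coefficient,
#' center`; one row per stratum uses the reserved covariate name
#' `.baseline_survival_5y` to carry \eqn{S_0(5)} in the `coefficient`
#' column. Reading and writing round-trip exactly.
#'
#' @param model A [ph_risk_model()].
#' @param path CSV file path.
#' @return `read_ph_risk_model()` returns a `ph_risk_model`;
#'   `write_ph_risk_model()` returns `path` invisibly.
#' @export
write_ph_risk_model <- function(model, path) {
  stopifnot(inherits(model, "ph_risk_model"))
  base_rows <- tibble(
    stratum = model$strata,
    covariate = ".baseline_survival_5y",
    coefficient = unname(model$baseline_survival),
    center = NA_real_
  )
  readr::write_csv(bind_rows(model$coefficients, base_rows), path)
  invisible(path)
}

#' @rdname write_ph_risk_model
#' @export
read_ph_risk_model <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  is_base <- tab$covariate == ".baseline_survival_5y"
  if (!any(is_base)) abort("coefficient table has no .baseline_survival_5y rows.")
  base <- tab[is_base, ]
  ph_risk_model(
    coefficients = tab[!is_base, ],
    baseline_survival = setNames(base$coefficient, base$stratum)
  )
}

#' Predicted 5-year risk from a stratified PH risk model
#'
#' Applies the published score to every participant: the linear predictor is
#' the centered covariate sum within the participant's stratum, and the risk
#' is \eqn{1 - S_0(5)^{\exp(lp)}}. Adds a `.risk` column.
#'
#' @param data Participant table containing every model covariate.
#' @param model A [ph_risk_model()].
#' @param stratum Name of the column identifying each participant's stratum;
#'   omit (`NULL`) for single-stratum models.
#' @return `data` with a `.risk` column of predicted 5-year event
#'   probabilities.
#' @export
predict_linear_ph_risk <- function(data, model, stratum = NULL) {
  stopifnot(is.data.frame(data), inherits(model, "ph_risk_model"))
  if (is.null(stratum)) {
    if (length(model$strata) > 1) {
      abort("multi-stratum model: supply the `stratum` column name.")
    }
    strat_val <- rep(model$strata, nrow(data))
  } else {
    if (!stratum %in% names(data)) {
      abort(paste0("stratum column `", stratum, "` not found."))
    }
    strat_val <- as.character(data[[stratum]])
    unknown <- setdiff(unique(strat_val), model$strata)
    if (length(unknown) > 0) {
      abort(paste0("participant stratum absent from model: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  risk <- rep(NA_real_, nrow(data))
  for (s in model$strata) {
    rows <- which(strat_val == s)
    if (length(rows) == 0) next
    cf <- model$coefficients[model$coefficients$stratum == s, ]
    miss <- setdiff(cf$covariate, names(data))
    if (length(miss) > 0) {
      abort(paste0("model covariate(s) missing from data: ",
                   paste(miss, collapse = ", ")))
    }
    lp <- rep(0, length(rows))
    for (j in seq_len(nrow(cf))) {
      x <- as.numeric(data[[cf$covariate[j]]][rows])
      if (anyNA(x)) abort("missing covariate values; run complete_case_filter() first.")
      lp <- lp + cf$coefficient[j] * (x - cf$center[j])
    }
    risk[rows] <- 1 - model$baseline_survival[[s]]^exp(lp)
  }
  mutate(as_tibble(data), .risk = risk)
}

# contiguous rank blocks: sizes differ by <= 1, larger blocks at higher
# groups; ties broken by (score, id)
.rank_groups <- function(score, id, n_groups) {
  n <- length(score)
  stopifnot(n_groups >= 1, n >= n_groups)
  ord <- order(score, id)
  q <- n %/% n_groups
  r <- n %% n_groups
  sizes <- c(rep(q, n_groups - r), rep(q + 1L, r))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), times = sizes)
  grp
}

#' Partition participants into ordered risk groups by score rank
#'
#' Sorts by `(score, id)` ascending and cuts into `n_groups` contiguous rank
#' blocks of near-equal size (sizes differ by at most 1, with the larger
#' blocks at the higher-risk end). Group 1 holds the lowest predicted risk
#' and group `n_groups` the highest; with the default of five groups these
#' are the familiar risk quintiles. Adds a `.risk_group` integer column.
#' Because only ranks matter, any strictly monotone transform of the scores
#' yields the identical partition.
#'
#' @param data Table with a score column (default `.risk`) and an `id`
#'   column for deterministic tie-breaking.
#' @param n_groups Number of groups (default 5 = quintiles).
#' @param score Name of the score column.
#' @return `data` with a `.risk_group` column.
#' @export
quintile_partition <- function(data, n_groups = 5, score = ".risk") {
  stopifnot(is.data.frame(data))
  if (n_groups < 1) abort("`n_groups` must be at least 1.")
  if (!score %in% names(data)) {
    abort(paste0("score column `", score, "` not found; compute risk scores first."))
  }
  if (nrow(data) < n_groups) abort("fewer participants than groups.")
  ids <- if ("id" %in% names(data)) data$id else seq_len(nrow(data))
  mutate(as_tibble(data),
         .risk_group = .rank_groups(data[[score]], ids, n_groups))
}

#' Subgroup sizes of a partition
#'
#' @param data Table with a `.risk_group` column.
#' @return Tibble with columns `risk_group` and `n`.
#' @export
subgroup_sizes <- function(data) {
  stopifnot(".risk_group" %in% names(data))
  data %>%
    count(risk_group = .data$.risk_group, name = "n") %>%
    arrange(.data$risk_group)
}

# --- decision-tree committee -------------------------------------------------

.model_covariates <- function(data, covariates = NULL) {
  covariates %||%
    setdiff(names(data), c("id", "arm", "event", "time", "replicate",
                           ".risk", ".risk_group"))
}

.as_model_frame <- function(data, covariates) {
  out <- as.data.frame(data[, covariates, drop = FALSE])
  for (j in seq_along(out)) {
    if (is.character(out[[j]])) out[[j]] <- factor(out[[j]])
  }
  out
}

#' Fit a bootstrap committee of classification trees
#'
#' Trains one pruned classification tree per bootstrap resample of the
#' (oversampled, class-balanced) training set, tunes the minimum leaf size
#' and cost-complexity pruning by cross-validation within each bootstrap,
#' limits every tree to at most `max_leaves` terminal nodes, scores each
#' tree's classification accuracy on the untouched test set, and marks the
#' tree with median test accuracy (lower median for even `B`) as the
#' committee's representative. Trees are grown with `rpart` (binary Gini
#' splits, cost-complexity pruning).
#'
#' A bootstrap that happens to contain a single outcome class is redrawn
#' (the retry count is recorded in the tuning table).
#'
#' @param train Balanced training table (after [oversample_minority()]).
#' @param test Untouched test table used only to score accuracy.
#' @param B Number of bootstrap resamples.
#' @param max_leaves Maximum number of terminal nodes per tree.
#' @param seed Optional integer seed.
#' @param covariates Covariate columns to use; defaults to every column
#'   except id/arm/event/time bookkeeping.
#' @param minbucket_grid Candidate minimum-leaf-size values for tuning.
#' @param xval Cross-validation folds used by rpart for pruning selection.
#' @return An object of class `tree_committee`.
#' @export
fit_tree_committee <- function(train, test, B = 30, max_leaves = 6,
                               seed = NULL, covariates = NULL,
                               minbucket_grid = c(10, 20, 40), xval = 10) {
  stopifnot(is.data.frame(train), is.data.frame(test), B >= 1, max_leaves >= 1)
  covariates <- .model_covariates(train, covariates)
  y_train <- factor(binary_outcome_label(train), levels = c(0, 1))
  y_test <- factor(binary_outcome_label(test), levels = c(0, 1))
  x_train <- .as_model_frame(train, covariates)
  x_test <- .as_model_frame(test, covariates)

  .with_seed(seed, {
    trees <- vector("list", B)
    tuning <- vector("list", B)
    acc <- numeric(B)
    for (b in seq_len(B)) {
      retries <- 0L
      repeat {
        idx <- sample.int(nrow(x_train), replace = TRUE)
        if (length(unique(y_train[idx])) == 2) break
        retries <- retries + 1L
      }
      df_b <- cbind(.label = y_train[idx], x_train[idx, , drop = FALSE])
      best <- NULL
      for (mb in minbucket_grid) {
        fit <- rpart::rpart(
          .label ~ ., data = df_b, method = "class",
          control = rpart::rpart.control(cp = 1e-4, xval = xval,
                                         minbucket = mb, maxsurrogate = 0)
        )
        ct <- fit$cptable
        ok <- which(ct[, "nsplit"] <= max_leaves - 1)
        i <- ok[which.min(ct[ok, "xerror"])]
        cand <- list(fit = fit, cp = ct[i, "CP"], xerror = ct[i, "xerror"],
                     minbucket = mb)
        if (is.null(best) || cand$xerror < best$xerror) best <- cand
      }
      tree <- rpart::prune(best$fit, cp = best$cp * 1.0000001)
      trees[[b]] <- tree
      acc[b] <- mean(predict(tree, x_test, type = "class") == y_test)
      tuning[[b]] <- tibble(
        bootstrap = b, minbucket = best$minbucket, cp = best$cp,
        xerror = best$xerror, n_leaves = sum(tree$frame$var == "<leaf>"),
        accuracy = acc[b], retries = retries
      )
    }
    # lower median: order statistic ceiling(B/2); stable order() breaks ties
    selected <- order(acc)[ceiling(B / 2)]
    structure(
      list(trees = trees, accuracy = acc, selected = selected,
           tuning = bind_rows(tuning), B = B, max_leaves = max_leaves,
           covariates = covariates, seed = seed),
      class = "tree_committee"
    )
  })
}

#' @export
print.tree_committee <- function(x, ...) {
  cat("<tree_committee>\n")
  cat(sprintf("  %d bootstrap trees (<= %d leaves); test accuracy %.3f-%.3f\n",
              x$B, x$max_leaves, min(x$accuracy), max(x$accuracy)))
  cat(sprintf("  selected tree #%d (median accuracy %.3f, %d leaves)\n",
              x$selected, x$accuracy[x$selected],
              sum(x$trees[[x$selected]]$frame$var == "<leaf>")))
  invisible(x)
}

#' Accuracy of the committee's selected (median) tree
#' @param committee A [fit_tree_committee()] result.
#' @return The selected tree's test accuracy.
#' @export
selected_tree_accuracy <- function(committee) {
  stopifnot(inherits(committee, "tree_committee"))
  committee$accuracy[committee$selected]
}

# descend an rpart tree explicitly (no surrogates; complete cases required)
# and return, for each row of newdata, the frame-row index of its leaf
.rpart_leaf_rows <- function(tree, newdata) {
  frame <- tree$frame
  if (all(frame$var == "<leaf>")) return(rep(1L, nrow(newdata)))
  splits <- tree$splits
  csplit <- tree$csplit
  node_ids <- as.integer(rownames(frame))
  # frame row -> row of `splits` holding its primary split
  split_row <- integer(nrow(frame))
  j <- 1L
  for (i in seq_len(nrow(frame))) {
    if (frame$var[i] != "<leaf>") {
      split_row[i] <- j
      j <- j + 1L + frame$ncompete[i] + frame$nsurrogate[i]
    }
  }
  xlev <- attr(tree, "xlevels")
  out <- integer(nrow(newdata))
  for (r in seq_len(nrow(newdata))) {
    i <- 1L
    repeat {
      v <- as.character(frame$var[i])
      if (v == "<leaf>") { out[r] <- i; break }
      s <- splits[split_row[i], ]
      x <- newdata[[v]][r]
      if (is.na(x)) abort("missing split covariate; complete cases required.")
      ncat <- s[["ncat"]]
      if (abs(ncat) == 1) {
        go_left <- if (ncat == -1) as.numeric(x) < s[["index"]]
                   else as.numeric(x) >= s[["index"]]
      } else {
        lev <- match(as.character(x), xlev[[v]])
        if (is.na(lev)) abort(paste0("unseen level for split covariate `", v, "`."))
        go_left <- csplit[s[["index"]], lev] == 1L
      }
      child <- node_ids[i] * 2L + if (go_left) 0L else 1L
      i <- match(child, node_ids)
    }
  }
  out
}

#' Subgroups from the selected tree's terminal nodes
#'
#' Sends each participant down the committee's selected tree and assigns the
#' terminal node as their subgroup. Leaves are renumbered 1..G by ascending
#' training event probability, so the highest group index is always the
#' highest-risk leaf. Group sizes are whatever the tree induces (they need
#' not be equal). Adds a `.risk_group` column; the leaf lookup table
#' (node, training event probability) is attached as the `leaves` attribute.
#'
#' @param data Table containing every split covariate.
#' @param committee A [fit_tree_committee()] result.
#' @return `data` with a `.risk_group` column.
#' @export
tree_subgroups <- function(data, committee) {
  stopifnot(is.data.frame(data), inherits(committee, "tree_committee"))
  tree <- committee$trees[[committee$selected]]
  x <- .as_model_frame(data, intersect(committee$covariates, names(data)))
  leaf_row <- .rpart_leaf_rows(tree, x)
  frame <- tree$frame
  leaf_idx <- which(frame$var == "<leaf>")
  # yval2 for a 2-class tree: class, counts (2), probabilities (2), node mass
  p_event <- frame$yval2[leaf_idx, 5]
  ord <- order(p_event, leaf_idx)
  group_of <- integer(nrow(frame))
  group_of[leaf_idx[ord]] <- seq_along(leaf_idx)
  leaves <- tibble(
    risk_group = seq_along(leaf_idx),
    node = as.integer(rownames(frame)[leaf_idx[ord]]),
    train_event_prob = p_event[ord]
  )
  out <- mutate(as_tibble(data), .risk_group = group_of[leaf_row])
  attr(out, "leaves") <- leaves
  out
}

#' Risk scores from the selected tree
#'
#' Leaf-level predicted event probabilities of the committee's selected
#' tree, added as a `.risk` column. These are the scores used when the
#' committee is assessed with threshold classification metrics.
#'
#' @inheritParams tree_subgroups
#' @return `data` with a `.risk` column.
#' @export
tree_risk_scores <- function(data, committee) {
  stopifnot(is.data.frame(data), inherits(committee, "tree_committee"))
  tree <- committee$trees[[committee$selected]]
  x <- .as_model_frame(data, intersect(committee$covariates, names(data)))
  mutate(as_tibble(data), .risk = unname(predict(tree, x, type = "prob")[, "1"]))
}

# --- probability-weighted random forest --------------------------------------

#' Fit a probability-weighted random forest
#'
#' A bagged ensemble of `n_trees` trees with per-split random feature
#' subsetting, each tree limited to `max_leaves` terminal nodes. Trees are
#' grown in regression mode on the 0/1 outcome label, so each tree's leaf
#' value is exactly the leaf's positive-class frequency and the ensemble
#' prediction is the arithmetic mean of per-tree positive-class
#' probabilities — each tree's vote weighted by its predicted probability
#' rather than a hard 0/1 majority. The feature-subset size (`mtry`) and
#' minimum leaf size (`nodesize`) are chosen by `cv_folds`-fold
#' cross-validation maximizing classification accuracy at the 0.5 threshold.
#'
#' @param train Balanced training table (after [oversample_minority()]).
#' @param n_trees Number of trees.
#' @param max_leaves Maximum terminal nodes per tree.
#' @param cv_folds Cross-validation folds for hyperparameter tuning.
#' @param seed Optional integer seed.
#' @param covariates Covariate columns to use.
#' @param mtry_grid,nodesize_grid Candidate hyperparameter values; defaults
#'   span the conventional \eqn{\sqrt{p}} up to \eqn{p/2} features per split.
#' @param tune If `FALSE`, skip cross-validation and use the first grid
#'   values.
#' @return An object of class `weighted_forest`.
#' @export
fit_weighted_forest <- function(train, n_trees = 100, max_leaves = 10,
                                cv_folds = 10, seed = NULL, covariates = NULL,
                                mtry_grid = NULL, nodesize_grid = c(5, 25),
                                tune = TRUE) {
  stopifnot(is.data.frame(train))
  if (n_trees < 1) abort("`n_trees` must be at least 1.")
  covariates <- .model_covariates(train, covariates)
  y <- as.numeric(binary_outcome_label(train))
  if (length(unique(y)) < 2) abort("training labels contain a single class.")
  x <- .as_model_frame(train, covariates)
  p <- ncol(x)
  mtry_grid <- mtry_grid %||% unique(pmax(1, c(floor(sqrt(p)), floor(p / 2))))

  .with_seed(seed, {
    grid <- expand.grid(mtry = mtry_grid, nodesize = nodesize_grid)
    if (tune && nrow(grid) > 1) {
      fold <- sample(rep_len(seq_len(cv_folds), nrow(x)))
      cv_acc <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        correct <- 0L
        for (f in seq_len(cv_folds)) {
          tr <- fold != f
          # regression mode on a 0/1 response is deliberate: leaf values are
          # positive-class frequencies, so silence the 5-unique-values warning
          fit <- suppressWarnings(randomForest::randomForest(
            x[tr, , drop = FALSE], y[tr], ntree = n_trees,
            maxnodes = max_leaves, mtry = grid$mtry[g],
            nodesize = grid$nodesize[g]
          ))
          pr <- predict(fit, x[!tr, , drop = FALSE])
          correct <- correct + sum((pr >= 0.5) == (y[!tr] == 1))
        }
        cv_acc[g] <- correct / nrow(x)
      }
      chosen <- which.max(cv_acc)
      tuning <- as_tibble(grid) %>% mutate(cv_accuracy = cv_acc)
    } else {
      chosen <- 1L
      tuning <- as_tibble(grid[1, , drop = FALSE]) %>%
        mutate(cv_accuracy = NA_real_)
    }
    forest <- suppressWarnings(randomForest::randomForest(
      x, y, ntree = n_trees, maxnodes = max_leaves,
      mtry = grid$mtry[chosen], nodesize = grid$nodesize[chosen]
    ))
    structure(
      list(forest = forest, tuning = tuning, chosen = chosen,
           mtry = grid$mtry[chosen], nodesize = grid$nodesize[chosen],
           n_trees = n_trees, max_leaves = max_leaves,
           covariates = covariates, seed = seed),
      class = "weighted_forest"
    )
  })
}

#' @export
print.weighted_forest <- function(x, ...) {
  cat("<weighted_forest>\n")
  cat(sprintf("  %d trees (<= %d leaves), mtry = %d, nodesize = %d\n",
              x$n_trees, x$max_leaves, x$mtry, x$nodesize))
  invisible(x)
}

#' Risk scores from a probability-weighted random forest
#'
#' Aggregated positive-class probabilities (mean of per-tree leaf
#' probabilities) for each participant, added as a `.risk` column; feed the
#' result to [quintile_partition()] for risk-quintile subgroups.
#'
#' @param data Table containing the forest's covariates.
#' @param forest A [fit_weighted_forest()] result.
#' @return `data` with a `.risk` column in \[0, 1\].
#' @export
forest_risk_scores <- function(data, forest) {
  stopifnot(is.data.frame(data), inherits(forest, "weighted_forest"))
  x <- .as_model_frame(data, intersect(forest$covariates, names(data)))
  pr <- pmin(1, pmax(0, unname(predict(forest$forest, x))))
  mutate(as_tibble(data), .risk = pr)
}
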