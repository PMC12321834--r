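# The eleven classical fingerprint-based classifiers, run under the same
# fold plan as the network so comparisons differ only in the learner.
#
# Each entry delegates to an installed implementation (rpart, class, e1071,
# glmnet, ranger, xgboost); AdaBoost, which has no installed provider, is a
# minimal SAMME over depth-1 rpart stumps. Hyperparameters are the
# providers' defaults (recorded in the registry) unless noted.

#' Registry of baseline classifiers
#'
#' Exactly eleven named models. Each entry records the backing
#' implementation and the hyperparameters used, so a run report is
#' self-describing.
#'
#' @return a tibble with columns `name`, `label`, `backend`, `params`
#'   (list-column).
#' @export
baseline_registry <- function() {
  tibble::tribble(
    ~name, ~label, ~backend, ~params,
    "decision_tree", "Decision Tree", "rpart",
      list(method = "class"),
    "nearest_neighbors", "Nearest Neighbors", "class::knn",
      list(k = 5),
    "linear_svm", "Linear SVM", "e1071::svm",
      list(kernel = "linear", cost = 1, probability = TRUE),
    "naive_bayes", "Naive Bayes", "e1071::naiveBayes",
      list(laplace = 1, features = "binary factors"),
    "logistic_regression", "Logistic Regression", "glmnet",
      list(alpha = 0, lambda = "1/n", family = "binomial"),
    "random_forest", "Random Forest", "ranger",
      list(num.trees = 500, probability = TRUE),
    "adaboost", "AdaBoost", "cmpnntox (SAMME, rpart stumps)",
      list(n_estimators = 50, max_depth = 1),
    "gradient_boosting", "Gradient Boosting", "xgboost",
      list(eta = 0.1, nrounds = 100, max_depth = 3, lambda = 0),
    "extra_trees", "Extra Trees", "ranger",
      list(splitrule = "extratrees", num.random.splits = 1,
           replace = FALSE, sample.fraction = 1, num.trees = 500),
    "lightgbm", "LightGBM-style (leaf-wise hist)", "xgboost",
      list(tree_method = "hist", grow_policy = "lossguide",
           max_leaves = 31, eta = 0.1, nrounds = 100),
    "xgboost", "XGBoost", "xgboost",
      list(eta = 0.3, nrounds = 100, max_depth = 6)
  )
}

# fit one learner; returns function(newx) -> P(class 1)
fit_baseline <- function(name, x, y, seed = 1L) {
  if (length(unique(y)) < 2) {
    stop_cmpnntox("single-class training fold", "cmpnntox_degenerate_fold_error")
  }
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  switch(name,
    decision_tree = {
      df <- as.data.frame(x); df$.y <- yf
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      function(nx) predict(fit, as.data.frame(nx))[, "1"]
    },
    nearest_neighbors = {
      function(nx) {
        pr <- class::knn(x, nx, yf, k = 5, prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == "1", p_win, 1 - p_win)
      }
    },
    linear_svm = {
      fit <- e1071::svm(x, yf, kernel = "linear", probability = TRUE)
      function(nx) attr(predict(fit, nx, probability = TRUE),
                        "probabilities")[, "1"]
    },
    naive_bayes = {
      xf <- as.data.frame(lapply(as.data.frame(x), factor,
                                 levels = c(0, 1)))
      fit <- e1071::naiveBayes(xf, yf, laplace = 1)
      function(nx) {
        nf <- as.data.frame(lapply(as.data.frame(nx), factor,
                                   levels = c(0, 1)))
        predict(fit, nf, type = "raw")[, "1"]
      }
    },
    logistic_regression = {
      fit <- glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                            lambda = 1 / nrow(x))
      function(nx) drop(predict(fit, nx, type = "response"))
    },
    random_forest = {
      df <- as.data.frame(x); df$.y <- yf
      fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                            num.trees = 500, seed = seed)
      function(nx) predict(fit, as.data.frame(nx))$predictions[, "1"]
    },
    adaboost = fit_samme(x, yf, n_estimators = 50),
    gradient_boosting = fit_xgb(x, y, list(eta = 0.1, max_depth = 3,
                                           lambda = 0), 100, seed),
    extra_trees = {
      df <- as.data.frame(x); df$.y <- yf
      fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                            num.trees = 500, splitrule = "extratrees",
                            num.random.splits = 1, replace = FALSE,
                            sample.fraction = 1, seed = seed)
      function(nx) predict(fit, as.data.frame(nx))$predictions[, "1"]
    },
    lightgbm = fit_xgb(x, y, list(eta = 0.1, tree_method = "hist",
                                  grow_policy = "lossguide", max_depth = 0,
                                  max_leaves = 31), 100, seed),
    xgboost = fit_xgb(x, y, list(eta = 0.3, max_depth = 6), 100, seed),
    stop_cmpnntox(paste0("unknown baseline: ", name),
                  "cmpnntox_registry_error")
  )
}

fit_xgb <- function(x, y, params, nrounds, seed) {
  params <- c(params, list(objective = "binary:logistic", nthread = 1,
                           seed = seed, verbosity = 0))
  fit <- xgboost::xgboost(data = x, label = y, params = params,
                          nrounds = nrounds, verbose = 0)
  function(nx) predict(fit, nx)
}

# discrete SAMME with depth-1 stumps; score = weighted vote fraction
fit_samme <- function(x, yf, n_estimators = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  df <- as.data.frame(x)
  y01 <- as.integer(yf) - 1L
  for (m in seq_len(n_estimators)) {
    df$.y <- yf
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1,
                                                       minsplit = 2))
    pred <- as.integer(predict(fit, df, type = "class")) - 1L
    err <- sum(w * (pred != y01)) / sum(w)
    if (err >= 0.5 || err <= 0) {
      if (err <= 0) { stumps <- c(stumps, list(fit)); alphas <- c(alphas, 10) }
      break
    }
    alpha <- log((1 - err) / err)
    w <- w * exp(alpha * (pred != y01))
    w <- w / sum(w)
    stumps <- c(stumps, list(fit)); alphas <- c(alphas, alpha)
  }
  function(nx) {
    nd <- as.data.frame(nx)
    votes <- vapply(stumps, function(s)
      as.integer(predict(s, nd, type = "class")) - 1L, integer(nrow(nd)))
    votes <- matrix(votes, nrow = nrow(nd))
    drop(votes %*% alphas) / sum(alphas)
  }
}

#' Run baseline classifiers under a fold plan
#'
#' Fits each requested baseline on the outer-training portion of every
#' fold, scores the outer test portion, and emits the full metric suite.
#' The same plan drives every model (and the network), so comparisons
#' differ only in the learner.
#'
#' @param data a compound tibble with `label` and a `fingerprint`
#'   list-column ([compute_fingerprints()] is called if absent).
#' @param plan a [make_fold_plan()] plan for `nrow(data)`.
#' @param models baseline names (default: all eleven).
#' @param threshold decision threshold for the hard-label metrics.
#' @param seed seed forwarded to the stochastic learners.
#' @return a tibble with one row per (model, repeat, fold) and the eight
#'   metric columns; per-fold predictions are kept in a `predictions`
#'   list-column.
#' @export
run_baselines <- function(data, plan, models = baseline_registry()$name,
                          threshold = 0.5, seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"), attr(plan, "n") == nrow(data))
  unknown <- setdiff(models, baseline_registry()$name)
  if (length(unknown)) {
    stop_cmpnntox(paste0("unknown baseline(s): ",
                         paste(unknown, collapse = ", ")),
                  "cmpnntox_registry_error")
  }
  if (!"fingerprint" %in% names(data)) data <- compute_fingerprints(data)
  x <- fingerprint_matrix(data)
  y <- as.numeric(data$label)
  out <- list()
  for (mdl in models) {
    for (i in seq_len(nrow(plan))) {
      tr <- plan$train_idx[[i]]; te <- plan$test_idx[[i]]
      scorer <- fit_baseline(mdl, x[tr, , drop = FALSE], y[tr], seed = seed)
      sc <- scorer(x[te, , drop = FALSE])
      rep_ <- evaluate_predictions(y[te], sc, threshold)
      out[[length(out) + 1L]] <- tibble::tibble(
        model = mdl, repeat_id = plan$repeat_id[i], fold = plan$fold[i],
        !!!rep_[metric_names],
        predictions = list(tibble::tibble(index = te, label = y[te],
                                          score = sc)))
    }
  }
  dplyr::bind_rows(out)
}

#' Comparison table across models
#'
#' Aggregates per-fold metric rows (from [run_baselines()] and/or
#' [run_crossval()]) into a model-by-metric table of mean (sd) values.
#'
#' @param fold_metrics tibble with a `model` column and metric columns.
#' @return a tibble, one row per model, `<metric>_mean` / `<metric>_sd`
#'   columns.
#' @export
comparison_table <- function(fold_metrics) {
  fold_metrics |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(dplyr::across(dplyr::any_of(metric_names),
                                   list(mean = ~round(mean(.x), 3),
                                        sd = ~round(stats::sd(.x), 3))),
                     .groups = "drop")
}
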