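quiet_opts()

test_that("fold plans partition the data and honour the nested sizes", {
  p10 <- make_fold_plan(10, seed = 4)
  expect_equal(vapply(p10$test_idx, length, 0L), rep(2L, 5))
  expect_setequal(unlist(p10$test_idx), 1:10)

  p1000 <- make_fold_plan(1000, seed = 4)
  expect_equal(vapply(p1000$train_idx, length, 0L), rep(800L, 5))
  # inner validation draws are 12.5% of outer training = 10% of the total
  for (i in 1:5) {
    expect_equal(vapply(p1000$inner_val[[i]], length, 0L), rep(100L, 5))
  }
  expect_identical(make_fold_plan(1000, seed = 4), p1000)
  expect_error(make_fold_plan(8), class = "cmpnntox_size_error")
})

test_that("repeated plans restart the outer loop with fresh shuffles", {
  p <- make_fold_plan(40, repeats = 3, seed = 9)
  expect_equal(nrow(p), 15)
  expect_true(assert_no_leakage(p))
  expect_false(identical(p$test_idx[[1]], p$test_idx[[6]]))
})

test_that("confusion counts match hand counts and degenerate thresholds", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6), 0.5)
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  all_pos <- confusion_counts(c(1, 0, 1), c(0.1, 0.2, 0.3), threshold = 0)
  expect_equal(all_pos$fn, 0L)
  expect_equal(all_pos$tn, 0L)
  expect_error(confusion_counts(c(1, 0), 0.5),
               class = "cmpnntox_alignment_error")
})

test_that("metric suite reproduces the printed formulas on hand cases", {
  perfect <- evaluate_predictions(rep(c(1, 0), each = 5),
                                  rep(c(0.9, 0.1), each = 5))
  for (m in c("acc", "kappa", "mcc", "f1", "auc", "balanced_accuracy")) {
    expect_equal(perfect[[m]], 1, label = m)
  }
  # TP=FN=TN=FP=1 plugged into the formulas by hand
  even <- evaluate_predictions(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6))
  expect_equal(even$acc, 0.5)
  expect_equal(even$balanced_accuracy, 0.5)
  expect_equal(even$kappa, 0)
  expect_equal(even$mcc, 0)
  expect_equal(even$f1, 0.5)
  # constant scores: single ROC segment, chance diagonal
  const <- evaluate_predictions(c(1, 0, 1, 0), rep(0.3, 4))
  expect_equal(const$auc, 0.5)
  expect_error(evaluate_predictions(c(1, 1), c(0.2, 0.9)),
               class = "cmpnntox_auc_undefined_error")
})

test_that("MCC with a zero denominator warns and reports zero", {
  expect_warning(
    r <- evaluate_predictions(c(1, 0, 1, 0), c(0.9, 0.8, 0.9, 0.6),
                              threshold = 0.1),
    "denominator")
  expect_equal(r$mcc, 0)
})

test_that("trapezoidal AUC equals brute-force pair counting, with ties", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))
    expect_equal(auc_trapezoid(labels, scores),
                 auc_paircount(labels, scores), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC agrees with an established ROC implementation", {
  set.seed(6)
  labels <- stats::rbinom(80, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- round(stats::runif(80), 2)
  expect_equal(auc_trapezoid(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-10)
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(7)
  rc <- roc_curve(stats::rbinom(50, 1, 0.4), round(stats::runif(50), 1))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("balanced accuracy equals accuracy on balanced symmetric cases", {
  # balanced classes, classifier symmetric across classes
  labels <- rep(c(1, 0), each = 10)
  scores <- c(rep(0.8, 8), rep(0.2, 2), rep(0.2, 8), rep(0.8, 2))
  r <- evaluate_predictions(labels, scores)
  expect_equal(r$balanced_accuracy, r$acc)
})

test_that("fold aggregation uses the sample standard deviation", {
  same <- tibble::tibble(auc = rep(0.9, 5), acc = rep(0.8, 5))
  ag <- aggregate_folds(same)
  expect_equal(ag$sd, c(0, 0))
  expect_error(aggregate_folds(same[1, ]),
               class = "cmpnntox_aggregation_error")
  vals <- tibble::tibble(auc = c(0.9, 0.92, 0.94))
  ag2 <- aggregate_folds(vals)
  expect_equal(ag2$sd, stats::sd(vals$auc))     # n-1 denominator
  expect_equal(ag2$mean, mean(vals$auc))
})

test_that("metric reports aggregate from report objects as well", {
  r1 <- evaluate_predictions(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  r2 <- evaluate_predictions(c(1, 0, 1, 0), c(0.6, 0.4, 0.2, 0.8))
  ag <- aggregate_folds(list(r1, r2))
  expect_equal(nrow(ag), 8)
  expect_equal(ag$mean[ag$metric == "auc"], mean(c(r1$auc, r2$auc)))
})
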