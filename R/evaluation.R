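# Repeated nested cross-validation splitting and the binary-classification
# metric suite (confusion counts, accuracy family, Cohen's kappa, Matthews
# correlation, trapezoidal ROC AUC).

#' Build a (repeated) nested cross-validation plan
#'
#' The index set is shuffled and partitioned into `k_outer` near-equal
#' outer folds; each fold serves once as the test set. For each outer fold,
#' `inner_reps` validation subsets of `inner_frac` of the outer-training
#' indices are drawn for tuning. With `repeats > 1` the whole outer loop is
#' repeated with fresh shuffles.
#'
#' @param n dataset size (>= 10).
#' @param k_outer outer folds (default 5).
#' @param inner_reps inner repetitions per outer fold (default 5).
#' @param inner_frac validation fraction of the outer-training set
#'   (default 0.125, i.e. 10% of the total under the 80/20 outer split).
#' @param repeats complete repetitions of the outer loop (default 1).
#' @param seed RNG seed; identical seeds give identical plans.
#' @return a `fold_plan`: tibble with one row per (repeat, outer fold) and
#'   list-columns `test_idx`, `train_idx`, `inner_val` (list of
#'   `inner_reps` index vectors drawn from `train_idx`).
#' @export
make_fold_plan <- function(n, k_outer = 5L, inner_reps = 5L,
                           inner_frac = 0.125, repeats = 1L, seed = 1L) {
  if (n < 10 || n < 2 * k_outer) {
    stop_cmpnntox("dataset too small to populate the nested folds",
                  "cmpnntox_size_error")
  }
  set.seed(seed)
  rows <- list()
  for (r in seq_len(repeats)) {
    perm <- sample.int(n)
    fold_of <- rep(seq_len(k_outer), length.out = n)
    for (k in seq_len(k_outer)) {
      test_idx <- sort(perm[fold_of == k])
      train_idx <- sort(setdiff(seq_len(n), test_idx))
      n_val <- max(1L, round(inner_frac * length(train_idx)))
      inner <- lapply(seq_len(inner_reps), function(j)
        sort(sample(train_idx, n_val)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_id = r, fold = k,
        test_idx = list(test_idx), train_idx = list(train_idx),
        inner_val = list(inner))
    }
  }
  plan <- dplyr::bind_rows(rows)
  attr(plan, "n") <- n
  attr(plan, "seed") <- seed
  class(plan) <- c("fold_plan", class(plan))
  assert_no_leakage(plan)
  plan
}

#' Assert fold-plan hygiene
#'
#' Checks, for every repeat: outer test sets are pairwise disjoint and
#' partition the index set; no test index appears in its own training set;
#' every inner validation set lies inside its outer-training set.
#' Called on every plan construction; exported for auditing.
#'
#' @param plan a `fold_plan`.
#' @return `TRUE`, invisibly; errors on violation.
#' @export
assert_no_leakage <- function(plan) {
  n <- attr(plan, "n")
  for (r in unique(plan$repeat_id)) {
    sub <- plan[plan$repeat_id == r, ]
    all_test <- unlist(sub$test_idx)
    if (anyDuplicated(all_test) || !setequal(all_test, seq_len(n))) {
      stop_cmpnntox("outer test sets do not partition the index set",
                    "cmpnntox_leakage_error")
    }
    for (i in seq_len(nrow(sub))) {
      if (length(intersect(sub$test_idx[[i]], sub$train_idx[[i]])) > 0) {
        stop_cmpnntox("train/test overlap in fold plan",
                      "cmpnntox_leakage_error")
      }
      for (v in sub$inner_val[[i]]) {
        if (!all(v %in% sub$train_idx[[i]])) {
          stop_cmpnntox("inner validation set leaks outside outer training",
                        "cmpnntox_leakage_error")
        }
      }
    }
  }
  invisible(TRUE)
}

#' Confusion counts at a probability threshold
#'
#' Scores at or above the threshold predict the toxic (positive) class.
#'
#' @param labels 0/1 vector.
#' @param scores probabilities in `[0, 1]`, same length.
#' @param threshold decision threshold (default 0.5).
#' @return a named list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop_cmpnntox("labels and scores have different lengths",
                  "cmpnntox_alignment_error")
  }
  stopifnot(is_binary_label(labels))
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1 & labels == 1),
       tn = sum(pred == 0 & labels == 0),
       fp = sum(pred == 1 & labels == 0),
       fn = sum(pred == 0 & labels == 1))
}

#' ROC curve by descending-threshold sweep
#'
#' Thresholds sweep the distinct score values in descending order (ties
#' grouped), tracing (FPR, TPR) from (0, 0) to (1, 1); both coordinates are
#' monotone non-decreasing.
#'
#' @inheritParams confusion_counts
#' @return a tibble with columns `fpr`, `tpr`, ordered along the sweep.
#' @export
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) {
    stop_cmpnntox("ROC needs both classes present", "cmpnntox_auc_undefined_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(l == 1); fp_cum <- cumsum(l == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble::tibble(fpr = c(0, fp_cum[last] / neg),
                 tpr = c(0, tp_cum[last] / pos))
}

#' Trapezoidal ROC AUC
#'
#' Area under the ROC curve by the trapezoidal rule over the
#' descending-threshold sweep; equals the probability that a random
#' positive is scored above a random negative (ties counted half).
#'
#' @inheritParams confusion_counts
#' @return the AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(labels, scores) {
  rc <- roc_curve(labels, scores)
  k <- nrow(rc)
  sum((rc$fpr[-1] - rc$fpr[-k]) * (rc$tpr[-1] + rc$tpr[-k]) / 2)
}

#' Full metric suite for one prediction set
#'
#' Computes the eight evaluation statistics: trapezoidal AUC, accuracy,
#' balanced accuracy, sensitivity, specificity, Cohen's kappa (via observed
#' and chance agreement), Matthews correlation and F1, plus the confusion
#' counts and the ROC curve. An MCC with a zero denominator is reported as
#' 0 with a warning.
#'
#' @inheritParams confusion_counts
#' @return a `metric_report` list: the eight metrics, `counts`,
#'   `threshold`, and `roc` (tibble of `fpr`, `tpr`).
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  if (length(unique(labels)) < 2) {
    stop_cmpnntox("all labels are one class; AUC is undefined",
                  "cmpnntox_auc_undefined_error")
  }
  cc <- confusion_counts(labels, scores, threshold)
  rep <- c(metrics_from_counts(cc),
           list(auc = auc_trapezoid(labels, scores)))
  structure(c(rep, list(counts = cc, threshold = threshold,
                        roc = roc_curve(labels, scores),
                        n = length(labels))),
            class = "metric_report")
}

metrics_from_counts <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  n <- tp + tn + fp + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  ba <- 0.5 * (sens + spec)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    rlang::warn("MCC denominator is zero; reporting 0")
    0
  } else (tp * tn - fp * fn) / mcc_den
  list(acc = acc, balanced_accuracy = ba, sensitivity = sens,
       specificity = spec, kappa = kappa, mcc = mcc, f1 = f1)
}

#' @export
#' @method print metric_report
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d  AUC %.3f  ACC %.3f  BA %.3f  kappa %.3f  MCC %.3f  F1 %.3f\n",
    x$n, x$auc, x$acc, x$balanced_accuracy, x$kappa, x$mcc, x$f1))
  invisible(x)
}

metric_names <- c("auc", "acc", "balanced_accuracy", "sensitivity",
                  "specificity", "kappa", "mcc", "f1")

#' Aggregate per-fold metric reports
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation of each
#' metric across folds; values are additionally rounded to 3 decimals in
#' the `mean_3` / `sd_3` display columns.
#'
#' @param reports a list of `metric_report`s (>= 2), or a tibble/data frame
#'   with metric columns (one row per fold).
#' @return a tibble with columns `metric`, `mean`, `sd`, `mean_3`, `sd_3`.
#' @export
aggregate_folds <- function(reports) {
  tab <- if (is.data.frame(reports)) {
    tibble::as_tibble(reports)
  } else {
    dplyr::bind_rows(lapply(reports, function(r) {
      tibble::as_tibble(r[intersect(metric_names, names(r))])
    }))
  }
  if (nrow(tab) < 2) {
    stop_cmpnntox("need at least 2 fold reports to aggregate",
                  "cmpnntox_aggregation_error")
  }
  tab |>
    dplyr::select(dplyr::any_of(metric_names)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(mean_3 = round(.data$mean, 3), sd_3 = round(.data$sd, 3))
}
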