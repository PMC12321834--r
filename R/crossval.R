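# Nested cross-validation for the network: the inner repetitions score
# hyperparameter candidates by mean validation AUC; the winner is retrained
# on the outer-training set with one early-stopping split and scored once
# on the outer test fold.

#' Nested cross-validation of the CMPNN
#'
#' For each outer fold: if more than one candidate configuration is given,
#' every candidate is trained on each inner split (outer-training minus the
#' inner validation draw, validated on the draw) and candidates are ranked
#' by mean inner validation AUC. The winning configuration is then
#' retrained on the outer-training set — holding out one fresh
#' `inner_frac`-sized split for early stopping — and scored on the outer
#' test fold.
#'
#' @param data labelled compound tibble (`smiles`, `label`).
#' @param plan a [make_fold_plan()] plan; built from
#'   `nrow(data)` and `seed` when `NULL`.
#' @param configs list of candidate [cmpnn_config()]s (default: the
#'   reference configuration only, in which case the inner scoring loop is
#'   skipped).
#' @param training a [training_config()].
#' @param threshold decision threshold for hard-label metrics.
#' @param seed seed for plan construction and the early-stopping splits.
#' @param quiet suppress progress messages.
#' @return a tibble with one row per (repeat, fold): the eight metrics, the
#'   selected configuration index, the fitted model and per-fold
#'   predictions as list-columns.
#' @export
run_crossval <- function(data, plan = NULL, configs = list(cmpnn_config()),
                         training = training_config(), threshold = 0.5,
                         seed = 1L, quiet = FALSE) {
  check_split(data, "full")
  if (is.null(plan)) plan <- make_fold_plan(nrow(data), seed = seed)
  stopifnot(inherits(plan, "fold_plan"), attr(plan, "n") == nrow(data))
  out <- list()
  for (i in seq_len(nrow(plan))) {
    tr <- plan$train_idx[[i]]; te <- plan$test_idx[[i]]
    chosen <- 1L
    if (length(configs) > 1) {
      inner_auc <- vapply(seq_along(configs), function(ci) {
        aucs <- vapply(plan$inner_val[[i]], function(vi) {
          fit_i <- setdiff(tr, vi)
          m <- cmpnn_fit(data[fit_i, ], data[vi, ], configs[[ci]],
                         training, quiet = TRUE)
          m$best_val_auc
        }, 0)
        mean(aucs)
      }, 0)
      chosen <- which.max(inner_auc)
      if (!quiet) {
        inform_quiet(sprintf("fold %d: config %d wins (inner AUC %.3f)",
                             i, chosen, max(inner_auc)))
      }
    }
    set.seed(seed + i)
    vi <- stratified_split(tr, data$label, 0.125)
    fit_i <- setdiff(tr, vi)
    mfit <- cmpnn_fit(data[fit_i, ], data[vi, ], configs[[chosen]],
                      training, quiet = quiet)
    pred <- predict(mfit, data[te, ], threshold = threshold)
    rep_ <- evaluate_predictions(data$label[te], pred$.pred, threshold)
    if (!quiet) {
      inform_quiet(sprintf("fold %d/%d: test AUC %.3f (stopped at epoch %d)",
                           i, nrow(plan), rep_$auc, max(mfit$log$epoch)))
    }
    out[[i]] <- tibble::tibble(
      model = "cmpnn", repeat_id = plan$repeat_id[i], fold = plan$fold[i],
      !!!rep_[metric_names], config_id = chosen,
      fitted = list(mfit),
      predictions = list(tibble::tibble(index = te,
                                        label = data$label[te],
                                        score = pred$.pred)))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "plan") <- plan
  res
}

# class-stratified validation draw so the early-stopping split always holds
# both classes when the pool does
stratified_split <- function(idx, labels, frac) {
  pos <- idx[labels[idx] == 1]
  neg <- idx[labels[idx] == 0]
  sort(c(sample(pos, max(1L, round(frac * length(pos)))),
         sample(neg, max(1L, round(frac * length(neg))))))
}
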