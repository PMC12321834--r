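# Training protocol: Adam on mean binary cross-entropy, linear warm-up then
# exponential learning-rate decay, early stopping on validation AUC.

#' Learning-rate schedule
#'
#' Linear warm-up from `init_lr` to `max_lr` over the warm-up steps, then
#' exponential decay reaching `final_lr` exactly at the last training step.
#' Continuous, with maximum exactly `max_lr` at the end of warm-up.
#'
#' @param step 0-based global batch counter (vectorized).
#' @param tc a [training_config()].
#' @param steps_per_epoch optimizer steps per epoch.
#' @return learning rate(s).
#' @export
lr_schedule <- function(step, tc, steps_per_epoch) {
  if (steps_per_epoch <= 0) {
    stop_cmpnntox("steps_per_epoch must be positive", "cmpnntox_config_error")
  }
  total <- tc$epochs * steps_per_epoch
  ws <- tc$warmup_epochs * steps_per_epoch
  step <- pmin(pmax(step, 0), total - 1)
  out <- numeric(length(step))
  warm <- step < ws
  out[warm] <- tc$init_lr + (tc$max_lr - tc$init_lr) * step[warm] / ws
  if (total - 1 > ws) {
    gamma <- (tc$final_lr / tc$max_lr)^(1 / (total - 1 - ws))
    out[!warm] <- tc$max_lr * gamma^(step[!warm] - ws)
  } else {
    out[!warm] <- tc$max_lr
  }
  out
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

check_split <- function(data, what) {
  if (nrow(data) == 0) {
    stop_cmpnntox(paste0(what, " split is empty"), "cmpnntox_empty_error")
  }
  if (!"label" %in% names(data) || anyNA(data$label)) {
    stop_cmpnntox(paste0(what, " split needs 0/1 labels"),
                  "cmpnntox_schema_error")
  }
}

#' Fit a CMPNN toxicity model
#'
#' Trains the communicative message-passing network on a labelled compound
#' table, minimizing mean binary cross-entropy with Adam under the warm-up /
#' exponential-decay learning-rate schedule. After each epoch the AUC on the
#' validation split is computed; training stops early after
#' `training$patience` epochs without improvement and the parameters from
#' the best validation epoch are returned.
#'
#' @param data labelled training tibble (columns `smiles`, `label`).
#' @param validation labelled validation tibble; must contain both classes.
#' @param config a [cmpnn_config()].
#' @param training a [training_config()].
#' @param smiles_col SMILES column name.
#' @param quiet suppress per-epoch progress messages.
#' @return a `cmpnn_model` with elements `params`, `config`, `training`,
#'   `log` (tibble: epoch, train_loss, val_auc, lr), `best_epoch`,
#'   `best_val_auc`, and the feature-schema hash.
#' @export
cmpnn_fit <- function(data, validation, config = cmpnn_config(),
                      training = training_config(), smiles_col = "smiles",
                      quiet = FALSE) {
  check_split(data, "training"); check_split(validation, "validation")
  if (length(unique(validation$label)) < 2) {
    stop_cmpnntox("validation split has a single class; AUC is undefined",
                  "cmpnntox_degenerate_class_error")
  }
  set.seed(training$seed)
  params <- init_params(config)
  graphs <- mol_graphs(data[[smiles_col]])
  y <- as.numeric(data$label)
  val_graphs <- mol_graphs(validation[[smiles_col]])
  val_batch <- batch_graphs(val_graphs)
  val_y <- as.numeric(validation$label)
  n <- length(graphs)
  bs <- min(training$batch_size, n)
  spe <- ceiling(n / bs)
  opt <- adam_init(params)
  gstep <- 0L
  best <- list(auc = -Inf, epoch = 0L, params = params)
  log <- vector("list", training$epochs)
  for (epoch in seq_len(training$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(spe)
    lr <- NA_real_
    for (bi in seq_len(spe)) {
      sel <- ord[((bi - 1) * bs + 1):min(bi * bs, n)]
      batch <- batch_graphs(graphs[sel])
      mask <- NULL
      if (config$dropout > 0) {
        mask <- matrix(stats::rbinom(length(sel) * config$ffn_hidden_size,
                                     1, 1 - config$dropout),
                       length(sel), config$ffn_hidden_size)
      }
      fw <- cmpnn_forward(params, batch, config, dropout_mask = mask,
                          keep_cache = TRUE)
      losses[bi] <- bce_loss(fw$yhat, y[sel])
      if (!is.finite(losses[bi])) {
        stop_cmpnntox("training loss diverged (non-finite)",
                      "cmpnntox_divergence_error")
      }
      grads <- cmpnn_backward(params, batch, config, fw, y[sel])
      lr <- lr_schedule(gstep, training, spe)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params; opt <- upd$state
      gstep <- gstep + 1L
    }
    val_pred <- cmpnn_forward(params, val_batch, config)$yhat
    val_auc <- auc_trapezoid(val_y, val_pred)
    log[[epoch]] <- tibble::tibble(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_auc = val_auc, lr = lr)
    if (!quiet) {
      inform_quiet(sprintf("epoch %3d  loss %.4f  val_auc %.4f  lr %.2e",
                           epoch, mean(losses), val_auc, lr))
    }
    if (val_auc > best$auc) {
      best <- list(auc = val_auc, epoch = epoch, params = params)
    } else if (epoch - best$epoch >= training$patience) {
      break
    }
  }
  structure(list(
    params = best$params, config = config, training = training,
    log = dplyr::bind_rows(log), best_epoch = best$epoch,
    best_val_auc = best$auc, schema_hash = feature_schema()$hash,
    n_train = n, n_validation = nrow(validation)
  ), class = "cmpnn_model")
}

#' @export
#' @method print cmpnn_model
print.cmpnn_model <- function(x, ...) {
  cat("<cmpnn_model> hidden", x$config$hidden_size, "depth", x$config$depth,
      "| trained", max(x$log$epoch), "epochs | best val AUC",
      sprintf("%.3f", x$best_val_auc), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Predict toxicity probabilities
#'
#' @param object a fitted `cmpnn_model`.
#' @param newdata a tibble with a SMILES column, or a character vector of
#'   SMILES.
#' @param threshold probability cut-off for the hard class (default 0.5).
#' @param smiles_col SMILES column name.
#' @param batch_size molecules per forward pass.
#' @param ... unused.
#' @return a tibble with `.pred` (probability of the toxic class) and
#'   `.pred_class` (0/1 at `threshold`), one row per input row.
#' @export
predict.cmpnn_model <- function(object, newdata, threshold = 0.5,
                                smiles_col = "smiles", batch_size = 200L,
                                ...) {
  smiles <- if (is.character(newdata)) newdata else newdata[[smiles_col]]
  graphs <- mol_graphs(smiles)
  chunks <- split(seq_along(graphs),
                  ceiling(seq_along(graphs) / batch_size))
  preds <- unlist(lapply(chunks, function(ix) {
    cmpnn_forward(object$params, batch_graphs(graphs[ix]),
                  object$config)$yhat
  }), use.names = FALSE)
  tibble::tibble(.pred = preds,
                 .pred_class = as.integer(preds >= threshold))
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the configuration, the feature-schema hash and all
#' parameters; loading restores bit-identical predictions on the same
#' platform. Loading refuses a checkpoint built under a different feature
#' schema.
#'
#' @param model a `cmpnn_model`.
#' @param path checkpoint file path.
#' @return `write_checkpoint` the path, invisibly; `read_checkpoint` the
#'   restored model.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cmpnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cmpnn_model") ||
      !identical(model$schema_hash, feature_schema()$hash)) {
    stop_cmpnntox("checkpoint does not match the current feature schema",
                  "cmpnntox_config_error")
  }
  model
}
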