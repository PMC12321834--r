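# CMPNN model definition: configuration, parameter initialization and the
# batched forward pass.
#
# The network follows the communicative message-passing scheme: directed
# edge states carry messages; node states aggregate incoming edge states by
# summation, amplified element-wise by a "booster" (the element-wise maximum
# over the same incoming edge states); edge states are then refreshed from
# the freshly updated node states through a rectified residual map. After K
# rounds, a GRU is run over each molecule's node states in canonical atom
# order and its outputs are summed into a fixed-length molecular embedding,
# scored by a two-layer sigmoid head.

#' Model configuration
#'
#' Hyperparameters of the message-passing network. The defaults are the
#' model's reference configuration: hidden width 300, depth 3, bias-free
#' message-passing linear maps, rectifier activation, two-layer head.
#'
#' @param hidden_size embedding width of node/edge states (default 300).
#' @param depth number of message-passing rounds K (default 3).
#' @param bias add offsets to the message-passing linear maps
#'   (default `FALSE`; the GRU gates and head offsets are kept regardless).
#' @param activation rectifier; only `"relu"` is supported.
#' @param ffn_num_layers head depth; the printed two-layer head is the only
#'   supported value.
#' @param ffn_hidden_size head width (default = `hidden_size`).
#' @param dropout dropout rate on the head's hidden layer during training
#'   (default 0).
#' @param booster_concat how the booster enters the node update:
#'   `"three_way"` (default) concatenates previous state, boosted message
#'   and booster; `"two_way"` drops the separate booster term.
#' @param atom_messages,undirected must stay `FALSE`: messages live on
#'   directed edges.
#' @return a `cmpnn_config` list.
#' @export
cmpnn_config <- function(hidden_size = 300L, depth = 3L, bias = FALSE,
                         activation = "relu", ffn_num_layers = 2L,
                         ffn_hidden_size = NULL, dropout = 0,
                         booster_concat = c("three_way", "two_way"),
                         atom_messages = FALSE, undirected = FALSE) {
  booster_concat <- match.arg(booster_concat)
  if (hidden_size < 1 || depth < 1) {
    stop_cmpnntox("hidden_size and depth must be positive",
                  "cmpnntox_config_error")
  }
  if (!identical(activation, "relu")) {
    stop_cmpnntox("only the rectifier activation is supported",
                  "cmpnntox_config_error")
  }
  if (ffn_num_layers != 2L) {
    stop_cmpnntox("the prediction head is the two-layer perceptron; ffn_num_layers must be 2",
                  "cmpnntox_config_error")
  }
  if (isTRUE(atom_messages) || isTRUE(undirected)) {
    stop_cmpnntox("atom_messages and undirected must be FALSE (directed edge messages)",
                  "cmpnntox_config_error")
  }
  if (dropout < 0 || dropout >= 1) {
    stop_cmpnntox("dropout must be in [0, 1)", "cmpnntox_config_error")
  }
  structure(list(
    hidden_size = as.integer(hidden_size), depth = as.integer(depth),
    bias = isTRUE(bias), activation = "relu",
    ffn_num_layers = 2L,
    ffn_hidden_size = as.integer(ffn_hidden_size %||% hidden_size),
    dropout = dropout, booster_concat = booster_concat,
    atom_messages = FALSE, undirected = FALSE
  ), class = "cmpnn_config")
}

#' Training configuration
#'
#' @param epochs maximum training epochs (default 60).
#' @param batch_size molecules per optimizer step (default 50).
#' @param warmup_epochs epochs of linear learning-rate warm-up (default 2).
#' @param init_lr,max_lr,final_lr learning-rate schedule anchors
#'   (defaults 1e-4, 1e-3, 1e-4).
#' @param patience early-stopping patience, in epochs without improvement of
#'   validation AUC (default 10).
#' @param seed run seed governing parameter initialization, batch shuffling
#'   and dropout.
#' @return a `cmpnn_training_config` list.
#' @export
training_config <- function(epochs = 60L, batch_size = 50L,
                            warmup_epochs = 2L, init_lr = 1e-4,
                            max_lr = 1e-3, final_lr = 1e-4,
                            patience = 10L, seed = 1L) {
  if (init_lr > max_lr || final_lr > max_lr) {
    stop_cmpnntox("init_lr and final_lr must not exceed max_lr",
                  "cmpnntox_config_error")
  }
  if (patience > epochs) {
    stop_cmpnntox("patience must not exceed epochs", "cmpnntox_config_error")
  }
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    warmup_epochs = as.integer(warmup_epochs),
    init_lr = init_lr, max_lr = max_lr, final_lr = final_lr,
    patience = as.integer(patience), seed = as.integer(seed)
  ), class = "cmpnn_training_config")
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Draws all learnable weights (Glorot-uniform matrices, zero offsets)
#' consistent with a configuration and the package feature schema. Uses the
#' current RNG state; seed it for reproducibility.
#'
#' @param config a [cmpnn_config()].
#' @return a named list of parameter matrices/vectors (class
#'   `cmpnn_params`).
#' @export
init_params <- function(config = cmpnn_config()) {
  fs <- feature_schema()
  h <- config$hidden_size
  f <- config$ffn_hidden_size
  cw <- if (config$booster_concat == "three_way") 3L else 2L
  p <- list(
    W_a = glorot(fs$atom_dim, h),
    W_b = glorot(fs$atom_dim + fs$bond_dim, h),
    W_n = glorot(cw * h, h),
    W_e = glorot(2L * h, h),
    Wz = glorot(h, h), Uz = glorot(h, h), bz = numeric(h),
    Wr = glorot(h, h), Ur = glorot(h, h), br = numeric(h),
    Wh = glorot(h, h), Uh = glorot(h, h), bh = numeric(h),
    W1 = glorot(h, f), b1 = numeric(f),
    W2 = glorot(f, 1L), b2 = numeric(1L)
  )
  if (config$bias) {
    p$ba <- numeric(h); p$bb <- numeric(h)
    p$bn <- numeric(h); p$be <- numeric(h)
  }
  structure(p, class = "cmpnn_params")
}

add_bias <- function(x, b) {
  if (is.null(b)) x else x + rep(b, each = nrow(x))
}

# element-wise max over incoming edge states, with the winning edge id per
# (node, dimension) cell for backpropagation; nodes without incoming edges
# get the zero vector (and id 0)
scatter_max_edges <- function(He, in_slots) {
  V <- nrow(in_slots); h <- ncol(He)
  B <- matrix(0, V, h); A <- matrix(0L, V, h)
  if (ncol(in_slots) == 0) return(list(B = B, A = A))
  has <- in_slots[, 1] > 0
  B[has, ] <- -Inf
  for (j in seq_len(ncol(in_slots))) {
    rows <- which(in_slots[, j] > 0)
    if (!length(rows)) break
    e <- in_slots[rows, j]
    cand <- He[e, , drop = FALSE]
    cur <- B[rows, , drop = FALSE]
    better <- cand > cur
    if (any(better)) {
      cur[better] <- cand[better]
      B[rows, ] <- cur
      Asub <- A[rows, , drop = FALSE]
      Asub[better] <- e[row(better)[better]]
      A[rows, ] <- Asub
    }
  }
  list(B = B, A = A)
}

# Batched forward pass. `batch` is a mol_graph_batch; returns predictions
# and, when keep_cache, every intermediate needed by the backward pass.
# dropout_keep is NULL (inference) or a 0/1 mask matrix for the head.
cmpnn_forward <- function(params, batch, config, dropout_mask = NULL,
                          keep_cache = FALSE) {
  if (batch$n_atoms == 0) {
    stop_cmpnntox("cannot run the network on an empty graph",
                  "cmpnntox_degenerate_input_error")
  }
  if (ncol(batch$atom_features) != nrow(params$W_a)) {
    stop_cmpnntox("graph feature width does not match model input projection",
                  "cmpnntox_config_error")
  }
  V <- batch$n_atoms
  K <- config$depth
  three <- config$booster_concat == "three_way"
  Xa <- batch$atom_features
  Za <- add_bias(Xa %*% params$W_a, params$ba)
  Hv <- relu(Za)
  has_edges <- batch$n_edges > 0
  if (has_edges) {
    Ein <- cbind(Xa[batch$edge_src, , drop = FALSE], batch$bond_features)
    Ze0 <- add_bias(Ein %*% params$W_b, params$bb)
    He <- relu(Ze0)
  } else {
    Ein <- NULL; Ze0 <- NULL
    He <- matrix(0, 0, config$hidden_size)
  }
  if (is.null(batch$in_slots)) {
    batch$in_slots <- incoming_slot_matrix(batch$edge_dst, V)
  }
  steps <- vector("list", K)
  for (t in seq_len(K)) {
    M <- scatter_add(He, batch$edge_dst, V)
    sm <- scatter_max_edges(He, batch$in_slots)
    Mp <- M * sm$B
    C <- if (three) cbind(Hv, Mp, sm$B) else cbind(Hv, Mp)
    Zn <- add_bias(C %*% params$W_n, params$bn)
    Hv_new <- relu(Zn)
    st <- list(Hv_prev = Hv, He_prev = He, M = M, B = sm$B, A = sm$A,
               C = C, zn_pos = Zn > 0)
    if (t < K && has_edges) {
      D <- cbind(Hv_new[batch$edge_dst, , drop = FALSE], He)
      Zee <- add_bias(D %*% params$W_e, params$be)
      He <- He + relu(Zee)
      st$D <- D
      st$zee_pos <- Zee > 0
    }
    if (keep_cache) steps[[t]] <- st
    Hv <- Hv_new
  }
  ro <- gru_readout_forward(params, Hv, batch, keep_cache)
  hmol <- ro$hmol
  A1 <- hmol %*% params$W1 + rep(params$b1, each = nrow(hmol))
  H1 <- relu(A1)
  H1d <- if (!is.null(dropout_mask)) {
    H1 * dropout_mask / (1 - config$dropout)
  } else H1
  logit <- drop(H1d %*% params$W2) + params$b2
  yhat <- sigmoid(logit)
  out <- list(yhat = yhat, logit = logit, hmol = hmol)
  if (keep_cache) {
    out$cache <- list(Xa = Xa, Za = Za, Ein = Ein, Ze0 = Ze0,
                      steps = steps, HvK = Hv, gru = ro$cache,
                      A1 = A1, H1d = H1d, dropout_mask = dropout_mask)
  }
  out
}

# GRU over each molecule's node states in canonical order; outputs summed
# per molecule.
gru_readout_forward <- function(params, Hv, batch, keep_cache = FALSE) {
  h <- ncol(Hv)
  M <- batch$n_mols
  nv <- batch$nv
  Hg <- matrix(0, M, h)
  hmol <- matrix(0, M, h)
  maxT <- max(nv)
  cache <- if (keep_cache) vector("list", maxT) else NULL
  for (t in seq_len(maxT)) {
    act <- which(nv >= t)
    idx <- batch$voff[act] + t
    x <- Hv[idx, , drop = FALSE]
    hp <- Hg[act, , drop = FALSE]
    z <- sigmoid(add_bias(x %*% params$Wz + hp %*% params$Uz, params$bz))
    r <- sigmoid(add_bias(x %*% params$Wr + hp %*% params$Ur, params$br))
    n <- tanh(add_bias(x %*% params$Wh + (r * hp) %*% params$Uh, params$bh))
    hn <- (1 - z) * n + z * hp
    Hg[act, ] <- hn
    hmol[act, ] <- hmol[act, , drop = FALSE] + hn
    if (keep_cache) cache[[t]] <- list(act = act, idx = idx, x = x, hp = hp,
                                       z = z, r = r, n = n)
  }
  list(hmol = hmol, cache = cache)
}
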