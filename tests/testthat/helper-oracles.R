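# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, no batching, no vectorized sweeps.

# Mann-Whitney AUC by brute-force pair enumeration (ties count half).
auc_paircount <- function(labels, scores) {
  p <- scores[labels == 1]
  q <- scores[labels == 0]
  tot <- 0
  for (a in p) {
    for (b in q) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(p) * length(q))
}

# Loop-based reference forward pass for a single molecule: no batching, no
# scatter ops; follows the same equations (K node updates, edge refresh
# after each of the first K-1, GRU readout in node order, two-layer head).
reference_forward <- function(params, graph, config) {
  h <- config$hidden_size
  K <- config$depth
  three <- config$booster_concat == "three_way"
  r0 <- function(x) pmax(x, 0)
  sg <- function(x) 1 / (1 + exp(-x))
  bias <- function(nm) if (is.null(params[[nm]])) 0 else params[[nm]]
  V <- graph$n_atoms
  E <- graph$n_edges
  Hv <- matrix(0, V, h)
  for (v in seq_len(V)) {
    Hv[v, ] <- r0(drop(graph$atom_features[v, , drop = FALSE] %*% params$W_a) +
                    bias("ba"))
  }
  He <- matrix(0, E, h)
  for (e in seq_len(E)) {
    x <- c(graph$atom_features[graph$edge_src[e], ], graph$bond_features[e, ])
    He[e, ] <- r0(drop(x %*% params$W_b) + bias("bb"))
  }
  for (t in seq_len(K)) {
    Hv_new <- matrix(0, V, h)
    for (v in seq_len(V)) {
      inc <- which(graph$edge_dst == v)
      if (length(inc)) {
        m <- colSums(He[inc, , drop = FALSE])
        b <- apply(He[inc, , drop = FALSE], 2, max)
      } else {
        m <- numeric(h); b <- numeric(h)
      }
      cvec <- if (three) c(Hv[v, ], m * b, b) else c(Hv[v, ], m * b)
      Hv_new[v, ] <- r0(drop(cvec %*% params$W_n) + bias("bn"))
    }
    if (t < K) {
      He_new <- He
      for (e in seq_len(E)) {
        d <- c(Hv_new[graph$edge_dst[e], ], He[e, ])
        He_new[e, ] <- He[e, ] + r0(drop(d %*% params$W_e) + bias("be"))
      }
      He <- He_new
    }
    Hv <- Hv_new
  }
  hs <- numeric(h)
  hm <- numeric(h)
  for (v in seq_len(V)) {
    x <- Hv[v, ]
    z <- sg(drop(x %*% params$Wz) + drop(hs %*% params$Uz) + params$bz)
    r <- sg(drop(x %*% params$Wr) + drop(hs %*% params$Ur) + params$br)
    nn <- tanh(drop(x %*% params$Wh) + drop((r * hs) %*% params$Uh) + params$bh)
    hs <- (1 - z) * nn + z * hs
    hm <- hm + hs
  }
  a1 <- r0(drop(hm %*% params$W1) + params$b1)
  sg(drop(a1 %*% params$W2) + params$b2)
}

# small labelled table with a fingerprint list-column built directly (no
# chemistry), for baseline tests
make_fp_table <- function(n, n_bits = 16, separable = TRUE, seed = 1) {
  set.seed(seed)
  label <- rep(c(0, 1), length.out = n)
  fp <- lapply(seq_len(n), function(i) {
    bits <- stats::rbinom(n_bits, 1, 0.3)
    if (separable) bits[1:4] <- label[i]
    as.integer(bits)
  })
  tibble::tibble(identifier = sprintf("t%03d", seq_len(n)),
                 smiles = NA_character_, label = label, fingerprint = fp)
}

# a tiny perfectly separable molecule set: nitroaromatics vs plain scaffolds
separable_molecules <- function() {
  tox <- c("Cc1ccc([N+](=O)[O-])cc1", "CCc1ccc([N+](=O)[O-])cc1",
           "OCc1ccc([N+](=O)[O-])cc1", "c1ccc([N+](=O)[O-])cc1",
           "CCCc1ccc([N+](=O)[O-])cc1", "NCc1ccc([N+](=O)[O-])cc1")
  non <- c("Cc1ccccc1", "CCc1ccccc1", "OCc1ccccc1", "c1ccccc1",
           "CCCc1ccccc1", "NCc1ccccc1")
  tibble::tibble(smiles = c(tox, non),
                 label = rep(c(1, 0), each = length(tox)))
}

quiet_opts <- function() options(cmpnntox.quiet = TRUE)
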