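quiet_opts()

small_config <- function(...) {
  cmpnn_config(hidden_size = 6, ffn_hidden_size = 4, ...)
}

test_that("message aggregation and booster match hand-computed values", {
  # two incoming edges carrying (1,2) and (3,4): sum (4,6), max (3,4)
  He <- rbind(c(1, 2), c(3, 4), c(5, 0))
  dst <- c(2L, 2L, 1L)
  M <- cmpnntox:::scatter_add(He, dst, 3)
  expect_equal(M[2, ], c(4, 6))
  expect_equal(M[1, ], c(5, 0))
  expect_equal(M[3, ], c(0, 0))          # no incoming edges: zero vector
  slots <- cmpnntox:::incoming_slot_matrix(dst, 3)
  sm <- cmpnntox:::scatter_max_edges(He, slots)
  expect_equal(sm$B[2, ], c(3, 4))
  expect_equal(sm$B[3, ], c(0, 0))
  # element-wise max across edges (1,5) and (3,2) -> (3,5)
  He2 <- rbind(c(1, 5), c(3, 2))
  sm2 <- cmpnntox:::scatter_max_edges(He2, cmpnntox:::incoming_slot_matrix(c(1L, 1L), 1))
  expect_equal(sm2$B[1, ], c(3, 5))
})

test_that("aggregation is invariant to incoming-edge order", {
  He <- matrix(stats::runif(10), 5, 2)
  dst <- c(1L, 1L, 2L, 1L, 2L)
  perm <- c(4L, 1L, 5L, 3L, 2L)
  M1 <- cmpnntox:::scatter_add(He, dst, 2)
  M2 <- cmpnntox:::scatter_add(He[perm, ], dst[perm], 2)
  expect_equal(M1, M2)
  B1 <- cmpnntox:::scatter_max_edges(He, cmpnntox:::incoming_slot_matrix(dst, 2))$B
  B2 <- cmpnntox:::scatter_max_edges(He[perm, ],
          cmpnntox:::incoming_slot_matrix(dst[perm], 2))$B
  expect_equal(B1, B2)
})

test_that("zero parameters give zero states and 0.5 predictions", {
  cfg <- small_config()
  set.seed(1)
  p <- init_params(cfg)
  for (nm in names(p)) p[[nm]][] <- 0
  b <- batch_graphs(mol_graphs(c("CCO", "C")))
  fw <- cmpnntox:::cmpnn_forward(p, b, cfg, keep_cache = TRUE)
  expect_true(all(fw$cache$steps[[1]]$Hv_prev == 0))   # h_v^0 under zero maps
  expect_true(all(fw$cache$steps[[1]]$He_prev == 0))
  expect_true(all(fw$hmol == 0))
  expect_equal(fw$yhat, c(0.5, 0.5))                   # sigmoid(0)
})

test_that("single-atom molecules run with zero edge states", {
  cfg <- small_config()
  set.seed(2)
  p <- init_params(cfg)
  b <- batch_graphs(mol_graphs("C"))
  fw <- cmpnntox:::cmpnn_forward(p, b, cfg, keep_cache = TRUE)
  expect_equal(nrow(fw$cache$steps[[1]]$He_prev), 0)
  expect_length(fw$yhat, 1)
  expect_true(fw$yhat > 0 && fw$yhat < 1)
})

test_that("forward pass is deterministic for fixed parameters", {
  cfg <- small_config()
  set.seed(3)
  p <- init_params(cfg)
  b <- batch_graphs(mol_graphs(c("CCO", "c1ccccc1")))
  f1 <- cmpnntox:::cmpnn_forward(p, b, cfg)$yhat
  f2 <- cmpnntox:::cmpnn_forward(p, b, cfg)$yhat
  expect_identical(f1, f2)
})

test_that("edge refresh is a rectified residual: identity under zero W_e, never decreasing", {
  cfg <- small_config()
  set.seed(4)
  p <- init_params(cfg)
  b <- batch_graphs(mol_graphs(c("CCO", "c1ccccc1")))
  p0 <- p; p0$W_e[] <- 0
  fw0 <- cmpnntox:::cmpnn_forward(p0, b, cfg, keep_cache = TRUE)
  expect_equal(fw0$cache$steps[[2]]$He_prev, fw0$cache$steps[[1]]$He_prev)
  fw <- cmpnntox:::cmpnn_forward(p, b, cfg, keep_cache = TRUE)
  for (t in 2:cfg$depth) {
    expect_true(all(fw$cache$steps[[t]]$He_prev >=
                    fw$cache$steps[[t - 1]]$He_prev - 1e-12))
  }
})

test_that("batched forward equals the loop-based reference on fixtures", {
  mols <- c(fixture_molecules()$smiles, "C#N", "CC(=O)O", "[Na+].[Cl-]",
            "C[C@H](N)C(=O)O")
  for (cfg in list(small_config(),
                   small_config(booster_concat = "two_way"),
                   small_config(bias = TRUE, depth = 2))) {
    set.seed(5)
    p <- init_params(cfg)
    gs <- mol_graphs(mols)
    batched <- cmpnntox:::cmpnn_forward(p, batch_graphs(gs), cfg)$yhat
    ref <- vapply(gs, function(g) reference_forward(p, g, cfg), 0)
    expect_equal(batched, ref, tolerance = 1e-5)
  }
})

test_that("predictions on a batch equal per-molecule predictions", {
  cfg <- small_config()
  set.seed(6)
  p <- init_params(cfg)
  gs <- mol_graphs(generate_compounds(n = 12, seed = 8)$smiles)
  together <- cmpnntox:::cmpnn_forward(p, batch_graphs(gs), cfg)$yhat
  alone <- vapply(gs, function(g)
    cmpnntox:::cmpnn_forward(p, batch_graphs(list(g)), cfg)$yhat, 0)
  expect_equal(together, alone, tolerance = 1e-5)
})

test_that("molecular embeddings have fixed width regardless of size", {
  cfg <- small_config()
  set.seed(7)
  p <- init_params(cfg)
  b <- batch_graphs(mol_graphs(c("C", paste0(rep("C", 50), collapse = ""))))
  fw <- cmpnntox:::cmpnn_forward(p, b, cfg)
  expect_equal(dim(fw$hmol), c(2L, cfg$hidden_size))
})

test_that("analytic gradients match central differences", {
  cfg <- cmpnn_config(hidden_size = 5, depth = 3, ffn_hidden_size = 4)
  set.seed(8)
  p <- init_params(cfg)
  b <- batch_graphs(mol_graphs(c("CCO", "O=[N+]([O-])c1ccccc1", "C", "C#N")))
  y <- c(1, 0, 1, 0)
  fw <- cmpnntox:::cmpnn_forward(p, b, cfg, keep_cache = TRUE)
  g <- cmpnntox:::cmpnn_backward(p, b, cfg, fw, y)
  loss_at <- function(pp)
    cmpnntox:::bce_loss(cmpnntox:::cmpnn_forward(pp, b, cfg)$yhat, y)
  eps <- 1e-6
  for (nm in names(p)) {
    for (i in unique(c(1L, length(p[[nm]]),
                       sample(length(p[[nm]]), min(3, length(p[[nm]])))))) {
      p_hi <- p; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- p; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste0("d", nm, "[", i, "]"))
    }
  }
})

test_that("prediction head is monotone in the pre-sigmoid score", {
  cfg <- small_config()
  set.seed(9)
  p <- init_params(cfg)
  b <- batch_graphs(mol_graphs("CCO"))
  base <- cmpnntox:::cmpnn_forward(p, b, cfg)
  p_up <- p; p_up$b2 <- p_up$b2 + 1
  up <- cmpnntox:::cmpnn_forward(p_up, b, cfg)
  expect_gt(up$yhat, base$yhat)
  expect_true(base$yhat > 0 && base$yhat < 1)
})

test_that("configuration guards reject unsupported settings", {
  expect_error(cmpnn_config(hidden_size = 0), class = "cmpnntox_config_error")
  expect_error(cmpnn_config(atom_messages = TRUE),
               class = "cmpnntox_config_error")
  expect_error(cmpnn_config(undirected = TRUE),
               class = "cmpnntox_config_error")
  expect_error(cmpnn_config(ffn_num_layers = 3),
               class = "cmpnntox_config_error")
  expect_error(cmpnn_config(activation = "tanh"),
               class = "cmpnntox_config_error")
  cfg <- small_config()
  set.seed(10)
  p <- init_params(cfg)
  g <- mol_graph("CCO")
  g$atom_features <- g$atom_features[, 1:10]
  expect_error(cmpnntox:::cmpnn_forward(p, batch_graphs(list(g)), cfg),
               class = "cmpnntox_config_error")
})
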