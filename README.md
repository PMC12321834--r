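# cmpnntox

Reproductive toxicity — a chemical's capacity to impair fertility or
embryonic/fetal development — is one of the costliest endpoints in
chemical safety assessment, and regulators increasingly expect *in
silico* screening before any animal study. `cmpnntox` is an R package
for building such screens from structure alone: it predicts a binary
reproductive-toxicity label (1 = toxic, 0 = non-toxic) directly from a
compound's SMILES string, for computational toxicologists and
cheminformaticians who want a graph-neural-network screen alongside the
classical fingerprint baselines it should be judged against.

## The model

The core is a **communicative message passing neural network (CMPNN)**
over the molecular graph `G = (V, E)` (atoms as nodes, each bond as two
directed edges). Node and edge states start as rectified projections of
atom/bond feature vectors and co-evolve over `K` rounds:

- message aggregation: `m_v^t = Σ_{u→v} h_{u→v}^{t-1}`
- message booster: `b_v^t = max_{u→v} h_{u→v}^{t-1}` (element-wise),
  `m'_v^t = m_v^t ⊙ b_v^t`
- node update: `h_v^t = ReLU(W_n [h_v^{t-1} ‖ m'_v^t ‖ b_v^t])`
- node–edge communication (rectified residual):
  `h_{u→v}^t = h_{u→v}^{t-1} + ReLU(W_e [h_v^t ‖ h_{u→v}^{t-1}])`

A GRU readout over the node states in canonical atom order is summed
into a fixed-length embedding `h_mol = Σ_v GRU(h_v^K)` and scored by a
two-layer head, `ŷ = σ(W₂ ReLU(W₁ h_mol + b₁) + b₂)`. Reference
configuration: hidden width 300, depth 3, bias-free message-passing
maps; training uses Adam on binary cross-entropy, batch size 50, a
linear warm-up (1e-4 → 1e-3) followed by exponential decay back to 1e-4,
and early stopping on validation AUC (patience 10).

Around the model: Morgan/ECFP4 fingerprints (2048 bits) and six
physicochemical descriptors via OpenBabel, eleven classical baseline
classifiers run under the identical fold plan, repeated nested
cross-validation (5 outer folds, 5 inner 12.5% validation draws), the
full metric suite (AUC, ACC, balanced accuracy, sensitivity,
specificity, Cohen's kappa, MCC, F1), a synthetic-molecule generator
with a planted noisy toxicophore rule, and a command-line interface.

## Worked example

```r
library(cmpnntox)

compounds <- generate_compounds(n = 200, noise = 0.05, seed = 1)
compounds[1:3, c("identifier", "smiles", "label")]
#> # A tibble: 3 × 3
#>   identifier smiles                                     label
#>   <chr>      <chr>                                      <dbl>
#> 1 syn_00001  CC(F)c1ccccc1CC(=O)Cc1ccc([N+](=O)[O-])cc1     1
#> 2 syn_00002  CCC(=O)NCCCCCCC(C)C                            0
#> 3 syn_00003  c1ccc([N+](=O)[O-])cc1CC(C)CCCN                1

model <- cmpnn_fit(
  data       = compounds[1:150, ],
  validation = compounds[151:170, ],
  config     = cmpnn_config(hidden_size = 64, ffn_hidden_size = 64),
  training   = training_config(epochs = 8, patience = 8, seed = 1),
  quiet      = TRUE)
model
#> <cmpnn_model> hidden 64 depth 3 | trained 8 epochs | best val AUC 0.938 at epoch 4

preds  <- predict(model, compounds[171:200, ])
report <- evaluate_predictions(compounds$label[171:200], preds$.pred)
report
#> <metric_report> n=30  AUC 0.991  ACC 0.867  BA 0.889  kappa 0.737  MCC 0.764  F1 0.857
tidy(report)
#> # A tibble: 8 × 2
#>   metric            value
#>   <chr>             <dbl>
#> 1 auc               0.991
#> 2 acc               0.867
#> 3 balanced_accuracy 0.889
#> 4 sensitivity       1
#> 5 specificity       0.778
#> 6 kappa             0.737
#> 7 mcc               0.764
#> 8 f1                0.857
```

The generator plants two toxicophores (a nitroaromatic group and an
ortho-phthalate diester) and flips 5% of labels, so an AUC near 1 on
held-out compounds means the network recovered the planted structural
rule through three rounds of message passing; ACC/kappa/MCC sit lower
because the 0.5 threshold and the label noise cap hard-label agreement.
`autoplot(report)` draws the ROC curve and `autoplot(model)` the
training trajectory. For full studies use `make_fold_plan()` +
`run_crossval()` (network) and `run_baselines()` (the eleven classical
models), then `comparison_table()` for a model-by-metric summary.

A command-line wrapper with subcommands `simulate | descriptors | train
| crossval | baselines | predict | report` is installed at
`system.file("cli", "cmpnntox", package = "cmpnntox")`.

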