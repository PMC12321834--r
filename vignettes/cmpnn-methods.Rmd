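---
title: "Predicting reproductive toxicity from molecular graphs: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reproductive toxicity from molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cmpnntox` predicts whether a small organic molecule is reproductively
toxic (a binary endpoint: 1 = toxic, 0 = non-toxic) directly from its
SMILES string. Its core is a communicative message passing neural network
(CMPNN) over the molecular graph; around it sit the pieces a QSAR study
needs: fingerprints and descriptors for classical comparators, a repeated
nested cross-validation protocol, a full binary-classification metric
suite, and a synthetic-molecule generator used to validate the whole
pipeline at desk scale.

## The model

A molecule is a directed graph $G = (V, E)$: heavy atoms are nodes, and
every chemical bond contributes two directed edges with identical bond
features. Initial states are rectified linear projections of the feature
vectors,
$$h_v^0 = \mathrm{ReLU}(W_a\,x_v), \qquad
  h_{u\to v}^0 = \mathrm{ReLU}(W_b\,[x_u \,\|\, e_{uv}]),$$
where $x_v$ encodes element, degree, formal charge, chirality tag,
attached-hydrogen count, hybridization, aromaticity and scaled atomic
mass, and $e_{uv}$ encodes bond order class, conjugation, ring membership
and a stereo slot. Hydrogens are implicit — encoded as per-atom counts,
not graph nodes — so a depth of $K$ hops always refers to heavy-atom
bonds.

Each of $K$ rounds then performs three steps. Messages aggregate over
incoming edges,
$$m_v^t = \sum_{u : u\to v \in E} h_{u\to v}^{t-1},$$
and a *message booster* amplifies the most informative bond
contributions through the element-wise maximum,
$$b_v^t = \max_{u : u\to v \in E} h_{u\to v}^{t-1}, \qquad
  m_v^{t\prime} = m_v^t \odot b_v^t.$$
The node update is a single rectified linear layer over the concatenation
$$h_v^t = \mathrm{ReLU}\!\left(W_n\,[\,h_v^{t-1} \,\|\, m_v^{t\prime}
  \,\|\, b_v^t\,]\right),$$
and edges are refreshed from the freshly updated node states through a
rectified residual ("node--edge communication"),
$$h_{u\to v}^t = h_{u\to v}^{t-1} +
  \mathrm{ReLU}\!\left(W_e\,[\,h_v^t \,\|\, h_{u\to v}^{t-1}\,]\right).$$

After round $K$ a gated recurrent unit runs over the node states in
canonical atom order and its outputs are summed into a fixed-length
molecular embedding, $h_{mol} = \sum_{v} \mathrm{GRU}(h_v^K)$, scored by
a two-layer head with dropout:
$\hat y = \sigma(W_2\,\mathrm{ReLU}(W_1 h_{mol} + b_1) + b_2)$.

### Design choices in the message passing

Several points of this scheme were genuinely open and were resolved as
follows.

* **Booster combination.** The node update concatenates the previous
  state, the boosted message *and* the booster itself (three-way). A
  two-way variant that drops the separate booster term is available as
  `cmpnn_config(booster_concat = "two_way")` and is exercised in the
  tests; the three-way form is the default because both the concatenation
  form of the update and the "use $m'$ in place of $m$" instruction can
  then hold simultaneously.
* **Edge update operand.** The communication step concatenates the
  *target* node state $h_v^t$ with the previous edge state and applies a
  single learned matrix $W_e$. The reverse-edge subtraction used by some
  directed-MPNN variants is deliberately not applied; nothing in the
  model description above requires it, and the rectified residual keeps
  edge states monotonically non-decreasing per component — a property the
  tests assert.
* **Final edge refresh.** Nothing consumes edge states after round $K$
  (the readout uses node states only), so the edge refresh is performed
  for $t = 1..K{-}1$. The loop-based reference implementation in the test
  suite follows the same convention, keeping the equivalence check
  meaningful.
* **Isolated nodes.** Single-atom species (including each fragment atom
  of salts like `[Na+].[Cl-]`) are legal: with no incoming edges both
  $m_v^t$ and $b_v^t$ are zero vectors and the update degenerates to
  $\mathrm{ReLU}(W_n [h_v^{t-1} \| 0 \| 0])$; the readout still runs.
* **GRU ordering.** The readout is order-sensitive by construction, so a
  deterministic order is required. Graphs are always built from the
  OpenBabel canonical form of the molecule, which makes node order — and
  therefore every prediction — invariant to how the input SMILES was
  spelled. This is asserted in the tests.
* **Ties in the booster.** When two incoming edges tie element-wise, the
  first edge in batch order wins; forward and backward passes share the
  same choice, so gradients stay consistent (verified against numerical
  differentiation).

### Hyperparameters

The reference configuration is hidden width 300, depth $K = 3$, bias-free
message-passing linear maps (the GRU gates and head offsets keep their
bias vectors — the bias flag governs the message-passing maps only), ReLU
activation, a two-layer head of the same width, dropout 0. Width 300 with
$K = 3$ lets every atom see a three-bond neighbourhood, enough for the
functional-group motifs that drive this endpoint, while staying clear of
over-smoothing; a width of 256 is the main alternative worth trying in
the tuning grid. Training defaults: 60 epochs, batch size 50, Adam on
mean binary cross-entropy, early stopping after 10 epochs without
validation-AUC improvement.

The learning rate warms up linearly from $10^{-4}$ to $10^{-3}$ over the
first two epochs of optimizer steps, then decays exponentially so that it
reaches $10^{-4}$ *exactly at the last scheduled step* (the decay rate is
solved per-step from the remaining step count). The curve is continuous
and attains its maximum exactly at the end of warm-up; all three anchors
are asserted exactly in the tests.

All randomness — parameter initialization (Glorot uniform), batch
shuffling, dropout masks, split draws — flows from the single run seed,
and fixed seeds reproduce training logs bit for bit.

## Evaluation protocol

`make_fold_plan()` implements repeated nested cross-validation: the index
set is shuffled into five outer folds (each serving once as the test
set); within each outer fold, five inner validation subsets of 12.5% of
the outer-training indices (10% of the total) are drawn for tuning. The
inner repetitions score hyperparameter candidates by mean validation AUC;
the winner is retrained on the outer-training set with one fresh
12.5% early-stopping split (class-stratified, so tiny splits keep both
classes) and scored once on the outer test fold. With a single candidate
configuration the inner scoring is a no-op and is skipped. "Repeated"
means complete repetitions of the outer loop under fresh shuffles
(`repeats`, default 1). Every plan is checked on construction: outer test
sets must partition the index set, never intersect their training sets,
and inner draws must stay inside their outer-training set.

The metric suite is implemented from the standard confusion-matrix
formulas: accuracy, balanced accuracy, sensitivity, specificity, F1,
Cohen's kappa via observed/chance agreement, and Matthews correlation
(reported as 0 with a warning when its denominator vanishes). The ROC
curve sweeps the distinct score values in descending order with ties
grouped, and AUC is the trapezoidal area under it — which equals the
Mann–Whitney pair-ordering probability, an identity the tests verify by
brute-force pair enumeration. Fold aggregation reports the arithmetic
mean and the *sample* (n−1) standard deviation, rounded to three decimals
for display.

## Chemistry layer

Structure handling delegates to OpenBabel (via ChemmineOB):
canonicalization, explicit-hydrogen topology, Ertl TPSA, Wildman–Crippen
logP, donor/acceptor counts, SMARTS matching, and ECFP circular
fingerprints. ECFP4 fingerprints are emitted at 4096 bits and folded to
the package's 2048-bit standard by OR-ing the two halves; fingerprints
are deterministic and identical across SMILES spellings of the same
molecule. Atom-level flags the R bindings do not expose (aromaticity,
formal charge, chirality tags) are recovered by scanning the atom tokens
of the canonical SMILES, which OpenBabel keeps aligned with its SDF atom
order; the package cross-checks that alignment by element symbol on every
parse. Ring membership is computed by bridge detection on the bond graph,
hybridization from bond multiplicities, and conjugation as "aromatic, or
both ends unsaturated" — package conventions, documented here because
different toolkits draw these lines slightly differently. Bond E/Z
annotations are not propagated into bond features (the stereo slot is
structurally present but always "none"); atom chirality tags are. The
model is strictly 2-D; enantiomer-specific effects are out of reach by
design.

SMILES are parsed as written — no desalting, standardization or tautomer
canonicalization. An optional largest-fragment switch exists for salt
handling but is off by default. Invalid SMILES are dropped with a logged
count rather than aborting, so large screens degrade gracefully.

## Baselines

Eleven classical classifiers run on the 2048-bit fingerprints under the
*same* fold plan as the network, so comparisons differ only in the
learner: decision tree (rpart), k-nearest neighbours, linear SVM,
Bernoulli naive Bayes, ridge logistic regression (glmnet), random forest
and extremely randomized trees (ranger), three gradient-boosting
configurations (xgboost: a classic depth-limited GBDT, a leaf-wise
histogram machine in the LightGBM style, and default XGBoost), and
AdaBoost. AdaBoost has no installed provider here, so a minimal SAMME
over depth-1 stumps is implemented in-package; every registry entry
records its backing implementation and hyperparameters so run reports are
self-describing. Baseline hyperparameters are the providers' defaults —
they are comparators, not the contribution — and are not tuned.

## The synthetic benchmark

Because the curated regulatory dataset behind the real application is not
redistributable, the package ships a generator that emulates its shape:
small organic molecules, near-balanced classes, and a structure-dependent
label with noise. Molecules are assembled by concatenating valence-safe
SMILES fragments (every fragment begins and ends with an atom that can
accept one more bond, so concatenation cannot produce invalid valences —
no sanitization loop is needed). The positive class is defined by two
planted toxicophores — a nitroaromatic group and an ortho-phthalate
diester, chemically evocative of this endpoint's literature but chosen
purely for testability — and ground truth comes from SMARTS matching on
the assembled molecule, not from the construction path, so accidental
matches in intended negatives are caught and resampled. Decoy fragments
(lone aromatic esters, aliphatic nitro groups, anilines) ensure the rule
cannot be learned from a single atom count. Labels then flip
independently at the noise rate $\varepsilon$ (default 0.05); the
pre-noise positive count is steered exactly to
`round(n * toxic_fraction)`.

What the generator does *not* emulate: the real data's structural
diversity (the fragment grammar spans a few thousand distinct molecules,
and repeated draws can produce duplicate structures on both sides of a
split), activity cliffs, assay noise structure, or any toxicological
truth. A green label-recovery test therefore shows that the pipeline can
learn a planted structural rule through graph message passing — it says
nothing about predictive performance on real regulatory data.

With $\varepsilon = 0$ a substructure-lookup classifier attains AUC 1 by
construction, the ceiling against which the network's label recovery is
judged: trained at the study conditions (n = 500, $\varepsilon = 0.05$,
one outer fold held out, 15 of the allowed 30 epochs — ample, since
validation AUC saturates within a few epochs on this rule), the network
must reach held-out AUC ≥ 0.85 while the same pipeline trained on
permuted labels stays near 0.5. The permuted control is evaluated on a
100-compound fold, so its AUC carries a sampling spread of roughly 0.08;
it is a chance control, not a precise quantity.

## Problem sizes and numerical notes

The test suite and the acceptance script run entirely on synthetic data
at desk scale: unit tests use hidden widths 4–16 and molecules of at most
~30 atoms; the label-recovery benchmark uses the full reference
configuration (hidden 300, depth 3) on 500 molecules; generator
convergence checks use 1000–2000 molecules. Forward/backward passes are
dense-matrix computations over the batched disjoint-union graph;
gradients are analytic and verified against central differences at
tolerance 1e-4, and the batched forward pass is verified against a plain
nested-loop reference at 1e-5. Binary cross-entropy is clamped with an
epsilon of 1e-12 against log-of-zero; sums use the natural left-to-right
BLAS order, so bit-level reproducibility is per-platform.

## Known limitations

* No 3-D information, conformers, or E/Z bond stereo in features.
* OpenBabel's perception differs from other toolkits for some charged
  species (zwitterions, nitro tautomers), which shifts TPSA/logP values
  there; neutral molecules agree to printed precision.
* The head is the fixed two-layer perceptron; deeper heads are rejected
  by configuration rather than silently reinterpreted.
* Baseline hyperparameters are provider defaults, not a tuned replication.
* The AdaBoost comparator is a minimal SAMME, not a full-featured
  implementation.
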